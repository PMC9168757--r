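# Seeded synthetic cohorts with planted structure: a bulk cohort carrying
# three expression programs (hot / cold / immunosuppressed) plus subtype-
# dependent survival, and a multi-sample single-cell cohort with planted cell
# types, marker genes, TF regulons and a ligand-receptor interaction. The
# ground-truth channel makes every downstream stage testable by parameter
# recovery rather than against protected patient data.

#' Bulk cohort simulation settings
#'
#' Defaults mirror a three-subtype liver-cancer cohort at reduced scale:
#' 40 hot, 48 cold and 30 immunosuppressed samples (the published cohort's
#' 120/144/89 proportions), 2000 genes of which 120 per subtype form its
#' expression program, a 2 log2-fold program shift over a baseline of 5 with
#' unit Gaussian noise, and a 2.5-fold excess hazard for the immunosuppressed
#' subtype.
#'
#' @param n_samples Named integer vector of samples per subtype
#'   (`hot`, `cold`, `suppressed`).
#' @param n_genes Total number of genes.
#' @param n_program_genes Program genes per subtype (disjoint across subtypes).
#' @param program_effect Log2-fold shift of a program gene in its own subtype.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param baseline_mean Baseline log2 expression.
#' @param hazard_multiplier Hazard ratio of the suppressed subtype versus the
#'   others.
#' @param baseline_hazard Exponential event rate per day for non-suppressed
#'   samples.
#' @param event_prob Probability that an observed failure is recorded as an
#'   event rather than censored.
#' @param horizon Administrative censoring horizon in days.
#' @param seed Integer seed.
#' @return A validated list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_samples = c(hot = 40L, cold = 48L, suppressed = 30L),
                            n_genes = 2000L,
                            n_program_genes = 120L,
                            program_effect = 2,
                            noise_sd = 1,
                            baseline_mean = 5,
                            hazard_multiplier = 2.5,
                            baseline_hazard = 1 / 1000,
                            event_prob = 0.7,
                            horizon = 3650,
                            seed = 1L) {
  stopifnot(
    length(n_samples) == 3,
    setequal(names(n_samples), c("hot", "cold", "suppressed")),
    all(n_samples >= 1), n_genes >= 1, n_program_genes >= 1,
    noise_sd > 0 || noise_sd == 0, hazard_multiplier > 0,
    baseline_hazard > 0, event_prob >= 0, event_prob <= 1
  )
  if (3 * n_program_genes > n_genes) {
    stop("n_program_genes x 3 subtypes exceeds n_genes", call. = FALSE)
  }
  structure(
    list(
      n_samples = n_samples[c("hot", "cold", "suppressed")],
      n_genes = as.integer(n_genes),
      n_program_genes = as.integer(n_program_genes),
      program_effect = program_effect, noise_sd = noise_sd,
      baseline_mean = baseline_mean, hazard_multiplier = hazard_multiplier,
      baseline_hazard = baseline_hazard, event_prob = event_prob,
      horizon = horizon, seed = as.integer(seed)
    ),
    class = "bulk_sim_config"
  )
}

#' Generate a bulk expression cohort with planted subtype programs
#'
#' Gene g in sample s is drawn as
#' `Normal(baseline_mean + program_effect * [g in program of subtype(s)],
#' noise_sd^2)` truncated at zero. Survival time is exponential with rate
#' `baseline_hazard * hazard_multiplier^[subtype == suppressed]`, censored
#' administratively at `horizon`, with observed failures flagged as events
#' with probability `event_prob`.
#'
#' The ground truth also carries the marker gene-set families the scoring
#' stage consumes: 24 liver genes (cold program), 35 repressed genes
#' (suppressed program), 28 activated-T genes (hot program), an immune family
#' spanning hot and suppressed programs, and a signal-free stromal family.
#'
#' @param config A [bulk_sim_config()].
#' @return A list with `expression` ([expr_matrix()]), `samples` (tibble:
#'   `sample_id`, `subtype_label`, `time`, `event`) and `truth` (planted maps
#'   and gene-set families).
#' @export
generate_bulk_cohort <- function(config = bulk_sim_config()) {
  stopifnot(inherits(config, "bulk_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  subtypes <- rep(names(config$n_samples), config$n_samples)
  n <- length(subtypes)
  samples <- sprintf("S%03d", seq_len(n))

  npg <- config$n_program_genes
  programs <- list(
    hot = genes[seq_len(npg)],
    cold = genes[npg + seq_len(npg)],
    suppressed = genes[2 * npg + seq_len(npg)]
  )
  stopifnot(!anyDuplicated(unlist(programs)))

  mu <- matrix(config$baseline_mean, config$n_genes, n, dimnames = list(genes, samples))
  for (st in names(programs)) {
    mu[programs[[st]], subtypes == st] <- config$baseline_mean + config$program_effect
  }
  vals <- pmax(mu + matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                           config$n_genes, n), 0)
  dimnames(vals) <- list(genes, samples)

  rate <- config$baseline_hazard *
    ifelse(subtypes == "suppressed", config$hazard_multiplier, 1)
  time <- rexp(n, rate = rate)
  event <- rbinom(n, 1, config$event_prob) == 1
  censored <- time > config$horizon
  time[censored] <- config$horizon
  event[censored] <- FALSE

  # liver = cold program subset, repressed = suppressed subset, activated-T =
  # hot subset, mirroring the published marker-set sizes (24 / 35 / 28).
  gene_sets <- list(
    liver = programs$cold[1:24],
    repressed = programs$suppressed[1:35],
    activatedT = programs$hot[1:28],
    immune = c(programs$hot[29:68], programs$suppressed[36:75]),
    stromal = genes[(3 * npg + 1):(3 * npg + 30)]
  )

  truth <- list(
    sample_subtype = stats::setNames(subtypes, samples),
    programs = programs,
    gene_sets = gene_sets
  )
  list(
    expression = expr_matrix(vals),
    samples = tibble::tibble(
      sample_id = samples, subtype_label = subtypes,
      time = time, event = event
    ),
    truth = truth
  )
}

#' Single-cell cohort simulation settings
#'
#' Defaults emulate a ten-sample tumor single-cell cohort: 3 hot, 4 cold and
#' 3 immunosuppressed samples of 500 cells each over five cell types
#' (hepatocyte, activated T, suppressed T, macrophage, fibroblast) whose
#' mixing proportions differ by sample group; 30 disjoint marker genes per
#' type with a 4 log2-fold shift; five transcription factors each driving a
#' 20-gene regulon of non-marker targets, with the first TF preferentially
#' active in suppressed T cells (the planted immunosuppression driver); and a
#' 30% multiplicative dropout.
#'
#' @param n_samples Number of single-cell samples.
#' @param sample_groups Group of each sample over `hot`/`cold`/`suppressed`.
#' @param cells_per_sample Cells drawn per sample.
#' @param n_genes Total genes.
#' @param markers_per_type Marker genes per cell type (disjoint).
#' @param marker_effect Expression shift of a marker in its own type.
#' @param n_tfs Number of transcription factors.
#' @param targets_per_regulon Targets per TF regulon (disjoint, non-marker).
#' @param regulon_effect Target shift when the TF is active in a cell.
#' @param target_type_effect Additional shift of a TF's targets in the TF's
#'   home cell type: regulon targets are part of that type's expression
#'   program (as the immunosuppression driver's targets are themselves
#'   repressed-T program genes), over and above the activity-driven shift.
#' @param tf_effect Shift of the TF's own gene when active.
#' @param tf_on_prob_active Probability the TF is active in its own cell type.
#' @param tf_on_prob_other Probability the TF is active elsewhere.
#' @param baseline_mean Baseline expression (log1p-like scale).
#' @param noise_sd Gaussian noise standard deviation.
#' @param dropout_rate Per-entry probability of a dropout zero.
#' @param seed Integer seed.
#' @return A validated list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_samples = 10L,
                          sample_groups = c("hot", "cold", "cold", "cold", "cold",
                                            "hot", "hot", "suppressed", "suppressed",
                                            "suppressed"),
                          cells_per_sample = 500L,
                          n_genes = 1000L,
                          markers_per_type = 30L,
                          marker_effect = 4,
                          n_tfs = 5L,
                          targets_per_regulon = 20L,
                          regulon_effect = 1.5,
                          target_type_effect = 1,
                          tf_effect = 2,
                          tf_on_prob_active = 0.9,
                          tf_on_prob_other = 0.35,
                          baseline_mean = 0.5,
                          noise_sd = 0.75,
                          dropout_rate = 0.3,
                          seed = 1L) {
  stopifnot(
    n_samples >= 1, length(sample_groups) == n_samples,
    all(sample_groups %in% c("hot", "cold", "suppressed")),
    cells_per_sample >= 1, dropout_rate >= 0, dropout_rate < 1,
    n_tfs >= 1, targets_per_regulon >= 1
  )
  cell_types <- c("Hepatocyte", "ActivatedT", "SuppressedT", "Macrophage", "Fibroblast")
  mixing <- rbind(
    hot        = c(Hepatocyte = 0.25, ActivatedT = 0.45, SuppressedT = 0.08,
                   Macrophage = 0.12, Fibroblast = 0.10),
    cold       = c(Hepatocyte = 0.70, ActivatedT = 0.06, SuppressedT = 0.06,
                   Macrophage = 0.08, Fibroblast = 0.10),
    suppressed = c(Hepatocyte = 0.20, ActivatedT = 0.07, SuppressedT = 0.45,
                   Macrophage = 0.18, Fibroblast = 0.10)
  )
  stopifnot(all(abs(rowSums(mixing) - 1) < 1e-9))
  needed <- 3L * 120L + 2L * markers_per_type + n_tfs +
    max(n_tfs - 1L, 0L) * targets_per_regulon + 10L
  if (needed > n_genes) stop("n_genes too small for the planted structure", call. = FALSE)
  structure(
    list(
      n_samples = as.integer(n_samples), sample_groups = sample_groups,
      cells_per_sample = as.integer(cells_per_sample),
      n_genes = as.integer(n_genes), cell_types = cell_types, mixing = mixing,
      markers_per_type = as.integer(markers_per_type), marker_effect = marker_effect,
      n_tfs = as.integer(n_tfs), targets_per_regulon = as.integer(targets_per_regulon),
      regulon_effect = regulon_effect, target_type_effect = target_type_effect,
      tf_effect = tf_effect,
      tf_on_prob_active = tf_on_prob_active, tf_on_prob_other = tf_on_prob_other,
      baseline_mean = baseline_mean, noise_sd = noise_sd,
      dropout_rate = dropout_rate, seed = as.integer(seed)
    ),
    class = "sc_sim_config"
  )
}

#' Generate a multi-sample single-cell cohort with planted structure
#'
#' Each cell's expression is its cell type's base program (markers shifted by
#' `marker_effect`), plus regulon effects (targets shifted by `regulon_effect`
#' and the TF gene by `tf_effect` in cells where the TF's latent activity is
#' on), plus Gaussian noise, multiplied by a Bernoulli(1 - dropout) mask and
#' truncated at zero. Suppressed-group samples over-represent the suppressed-T
#' type. A planted ligand-receptor interaction pairs a macrophage marker
#' (ligand) with a suppressed-T marker (receptor); decoy pairs are drawn from
#' signal-free genes.
#'
#' @param config An [sc_sim_config()].
#' @return List with `expression` ([expr_matrix()]), `cells` (tibble:
#'   `cell_id`, `sample_id`, `cell_type`, `group_label`) and `truth` (marker
#'   sets, regulons, driver TF, gene-set families, ligand-receptor pairs,
#'   latent TF activity).
#' @export
generate_sc_cohort <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  types <- config$cell_types
  mk <- config$markers_per_type

  # Gene layout is aligned with generate_bulk_cohort()'s program blocks
  # (120 genes per subtype program) so the two simulated cohorts share gene
  # semantics: activated-T markers sit in the hot program block, hepatocyte
  # markers in the cold block, suppressed-T markers — and the driver TF's
  # targets — in the suppressed block. A classifier trained on one cohort is
  # then meaningful on the other, as it is for real tumors.
  block <- 120L
  if (mk + config$targets_per_regulon > block) {
    stop("markers_per_type + targets_per_regulon must fit a 120-gene program block",
         call. = FALSE)
  }
  markers <- list(
    ActivatedT = genes[seq_len(mk)],
    Hepatocyte = genes[block + seq_len(mk)],
    SuppressedT = genes[2L * block + seq_len(mk)],
    Macrophage = genes[3L * block + seq_len(mk)],
    Fibroblast = genes[3L * block + mk + seq_len(mk)]
  )[types]
  offset <- 3L * block + 2L * mk
  tf_genes <- genes[offset + seq_len(config$n_tfs)]
  offset <- offset + config$n_tfs
  # driver TF targets live inside the suppressed program block, right after
  # the suppressed-T markers; other regulons draw from unclaimed genes
  regulons <- stats::setNames(lapply(seq_len(config$n_tfs), function(i) {
    if (i == 1) {
      genes[2L * block + mk + seq_len(config$targets_per_regulon)]
    } else {
      genes[offset + (i - 2) * config$targets_per_regulon +
              seq_len(config$targets_per_regulon)]
    }
  }), tf_genes)
  # each TF is preferentially active in one cell type; the first drives the
  # suppressed-T program (the immunosuppression driver the pipeline must find)
  tf_type <- stats::setNames(types[c(3, 2, 4, 5, 1)][seq_len(config$n_tfs)], tf_genes)

  n_cells_total <- config$n_samples * config$cells_per_sample
  sample_ids <- sprintf("SC%02d", seq_len(config$n_samples))
  cell_sample <- rep(sample_ids, each = config$cells_per_sample)
  cell_group <- rep(config$sample_groups, each = config$cells_per_sample)
  cell_type <- character(n_cells_total)
  for (i in seq_len(config$n_samples)) {
    idx <- which(cell_sample == sample_ids[i])
    probs <- config$mixing[config$sample_groups[i], types]
    cell_type[idx] <- sample(types, length(idx), replace = TRUE, prob = probs)
  }
  cell_ids <- sprintf("C%05d", seq_len(n_cells_total))

  mu <- matrix(config$baseline_mean, config$n_genes, n_cells_total,
               dimnames = list(genes, cell_ids))
  for (ty in types) {
    mu[markers[[ty]], cell_type == ty] <-
      config$baseline_mean + config$marker_effect
  }
  tf_on <- matrix(FALSE, config$n_tfs, n_cells_total,
                  dimnames = list(tf_genes, cell_ids))
  for (tf in tf_genes) {
    home <- cell_type == tf_type[[tf]]
    p_on <- ifelse(home, config$tf_on_prob_active, config$tf_on_prob_other)
    on <- runif(n_cells_total) < p_on
    tf_on[tf, ] <- on
    mu[tf, on] <- mu[tf, on] + config$tf_effect
    mu[regulons[[tf]], on] <- mu[regulons[[tf]], on] + config$regulon_effect
    # targets belong to the home type's program: shifted there regardless of
    # the TF's instantaneous activity
    mu[regulons[[tf]], home] <- mu[regulons[[tf]], home] + config$target_type_effect
  }
  vals <- mu + matrix(rnorm(config$n_genes * n_cells_total, sd = config$noise_sd),
                      config$n_genes, n_cells_total)
  mask <- matrix(runif(config$n_genes * n_cells_total) >= config$dropout_rate,
                 config$n_genes, n_cells_total)
  vals <- pmax(vals * mask, 0)
  dimnames(vals) <- list(genes, cell_ids)

  # score gene-set families defined on the planted programs, mirroring the
  # published set sizes (24 liver / 35 repressed / 28 activated-T)
  gene_sets <- list(
    liver = markers$Hepatocyte[1:24],
    repressed = c(markers$SuppressedT, regulons[[tf_genes[1]]][1:5]),
    activatedT = markers$ActivatedT[1:28],
    immune = c(markers$ActivatedT, markers$SuppressedT),
    stromal = markers$Fibroblast
  )

  decoy_start <- offset + max(config$n_tfs - 1L, 0L) * config$targets_per_regulon + 1
  decoys <- genes[seq(decoy_start, min(decoy_start + 7, config$n_genes))]
  lr_pairs <- tibble::tibble(
    pair_id = c("LR_planted", paste0("LR_decoy", seq_len(4))),
    ligand = c(markers$Macrophage[1], decoys[1:4]),
    receptor = c(markers$SuppressedT[1], decoys[5:8]),
    planted = c(TRUE, rep(FALSE, 4))
  )

  truth <- list(
    cell_type = stats::setNames(cell_type, cell_ids),
    sample_group = stats::setNames(config$sample_groups, sample_ids),
    markers = markers,
    tf_genes = tf_genes,
    regulons = regulons,
    tf_type = tf_type,
    driver_tf = tf_genes[1],
    suppressed_program = c(markers$SuppressedT, regulons[[tf_genes[1]]]),
    gene_sets = gene_sets,
    lr_pairs = lr_pairs,
    tf_on = tf_on
  )
  list(
    expression = expr_matrix(vals),
    cells = tibble::tibble(
      cell_id = cell_ids, sample_id = cell_sample,
      cell_type = cell_type, group_label = cell_group
    ),
    truth = truth
  )
}

#' Score inferred results against the planted ground truth
#'
#' Computes the adjusted Rand index between inferred and planted labels and/or
#' precision, recall and F1 of a recovered gene list against a planted one.
#'
#' @param inferred Named vector of inferred labels (names = observation ids),
#'   or `NULL`.
#' @param truth_labels Named vector of planted labels, or `NULL`.
#' @param inferred_genes Character vector of recovered genes, or `NULL`.
#' @param truth_genes Character vector of planted genes, or `NULL`.
#' @return A tibble with one row per metric (`metric`, `value`, `n`).
#' @export
truth_scorecard <- function(inferred = NULL, truth_labels = NULL,
                            inferred_genes = NULL, truth_genes = NULL) {
  rows <- list()
  if (!is.null(inferred) && !is.null(truth_labels)) {
    if (is.null(names(inferred)) || is.null(names(truth_labels)) ||
        !setequal(names(inferred), names(truth_labels))) {
      stop("inferred and truth labels must share the same observation ids", call. = FALSE)
    }
    truth_labels <- truth_labels[names(inferred)]
    ari <- mclust::adjustedRandIndex(as.character(inferred), as.character(truth_labels))
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = "ari", value = ari, n = length(inferred)
    )
  }
  if (!is.null(inferred_genes) && !is.null(truth_genes)) {
    tp <- length(intersect(inferred_genes, truth_genes))
    prec <- if (length(inferred_genes) > 0) tp / length(inferred_genes) else NA_real_
    rec <- if (length(truth_genes) > 0) tp / length(truth_genes) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
      2 * prec * rec / (prec + rec)
    } else {
      0
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = c("precision", "recall", "f1"),
      value = c(prec, rec, f1),
      n = length(truth_genes)
    )
  }
  if (length(rows) == 0) stop("nothing to score", call. = FALSE)
  dplyr::bind_rows(rows)
}
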