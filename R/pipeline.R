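# End-to-end orchestration: simulate (or ingest) -> subtype -> score -> DEG ->
# panel -> single-cell enrichment, co-expression, regulons, interactions ->
# survival. Stages are coupled through files under the output directory so any
# stage can be re-run and audited; a master seed propagates to every
# stochastic stage by fixed offsets; a JSON manifest records parameters,
# seeds, per-stage status and warnings.

#' Default pipeline configuration
#'
#' Stage toggles plus per-stage parameter blocks, all matching the
#' module-level defaults. With `simulate = TRUE` the synthetic generators
#' provide the inputs; otherwise `paths` must name the input files.
#'
#' @param seed Master seed.
#' @param simulate Use the synthetic generators for input data.
#' @param stages Character vector of stages to run.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE,
                            stages = c("simulate", "subtype", "score", "deg",
                                       "panel", "enrich", "coexpr", "regulon",
                                       "interact", "survival")) {
  structure(
    list(
      seed = as.integer(seed), simulate = simulate, stages = stages,
      paths = list(),
      bulk_sim = list(), sc_sim = list(),
      subtype = list(k_range = 2:6, mad_threshold = 1.0, n_runs = 30L),
      score = list(alpha = 0.25),
      deg = list(fc_cut = 1, q_cut = 0.05),
      panel = list(n_min = 30L, n_max = 126L, step = 3L),
      coexpr = list(pseudocell_size = 10L, min_module_size = 20L,
                    mm_min = 0.7, gs_min = 0.6),
      regulon = list(rho_min = 0.3, min_targets = 10L, top_frac = 0.05,
                     q_max = 0.05, hub_cell_type = "SuppressedT"),
      interact = list(n_perm = 1000L, min_frac = 0.1),
      survival = list(target_class = "suppressed")
    ),
    class = "pipeline_config"
  )
}

#' Run the integrated pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV/JSON
#' outputs under `out_dir` plus a `manifest.json` with parameters, seeds and
#' per-stage status. A failing stage halts the run; the manifest keeps the
#' failure marker and earlier outputs are retained.
#'
#' @param config A [pipeline_config()] (or a YAML file path with the same
#'   structure).
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- utils::modifyList(pipeline_config(), raw)
    class(config) <- "pipeline_config"
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("immunotype")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[setdiff(names(config), c("paths"))],
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  runner <- list(
    simulate = stage_simulate, subtype = stage_subtype, score = stage_score,
    deg = stage_deg, panel = stage_panel, enrich = stage_enrich,
    coexpr = stage_coexpr, regulon = stage_regulon, interact = stage_interact,
    survival = stage_survival
  )
  for (st in config$stages) {
    warns <- character(0)
    status <- "ok"
    msg <- NULL
    withCallingHandlers(
      tryCatch(
        runner[[st]](config, state, out_dir),
        error = function(e) {
          status <<- "failed"
          msg <<- conditionMessage(e)
        }
      ),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    manifest$stages[[st]] <- list(status = status, warnings = warns,
                                  message = msg)
    if (status == "failed") break
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

load_bulk <- function(config, state, out_dir) {
  if (is.null(state$bulk)) {
    state$bulk <- list(
      expression = read_expression_matrix(file.path(out_dir, "bulk_matrix.tsv")),
      samples = read_annotation(file.path(out_dir, "bulk_samples.tsv"), "sample")
    )
  }
  state$bulk
}

load_sc <- function(config, state, out_dir) {
  if (is.null(state$sc)) {
    state$sc <- list(
      expression = read_expression_matrix(file.path(out_dir, "sc_matrix.tsv")),
      cells = read_annotation(file.path(out_dir, "sc_cells.tsv"), "cell")
    )
  }
  state$sc
}

stage_simulate <- function(config, state, out_dir) {
  bulk <- generate_bulk_cohort(do.call(bulk_sim_config, c(
    config$bulk_sim, list(seed = derive_seed(config$seed, 1L))
  )))
  sc <- generate_sc_cohort(do.call(sc_sim_config, c(
    config$sc_sim, list(seed = derive_seed(config$seed, 2L))
  )))
  write_expression_matrix(bulk$expression, file.path(out_dir, "bulk_matrix.tsv"))
  readr::write_tsv(
    dplyr::mutate(bulk$samples, event = as.integer(.data$event)),
    file.path(out_dir, "bulk_samples.tsv")
  )
  write_expression_matrix(sc$expression, file.path(out_dir, "sc_matrix.tsv"))
  readr::write_tsv(sc$cells, file.path(out_dir, "sc_cells.tsv"))
  write_gene_sets(sc$truth$gene_sets, file.path(out_dir, "score_sets.gmt"))
  write_gene_sets(bulk$truth$gene_sets, file.path(out_dir, "bulk_score_sets.gmt"))
  readr::write_tsv(sc$truth$lr_pairs, file.path(out_dir, "lr_pairs.tsv"))
  writeLines(sc$truth$tf_genes, file.path(out_dir, "tfs.txt"))
  state$bulk <- bulk
  state$sc <- sc
  invisible(NULL)
}

stage_subtype <- function(config, state, out_dir) {
  bulk <- load_bulk(config, state, out_dir)
  res <- nmf_subtype(
    bulk$expression, k_range = config$subtype$k_range,
    mad_threshold = config$subtype$mad_threshold,
    n_runs = config$subtype$n_runs, seed = derive_seed(config$seed, 3L)
  )
  state$subtyping <- res
  readr::write_tsv(subtype_labels(res), file.path(out_dir, "subtype_labels.tsv"))
  readr::write_tsv(tidy(res), file.path(out_dir, "cophenetic.tsv"))
  for (k in res$k_range) {
    cm <- res$per_k[[as.character(k)]]$consensus
    readr::write_tsv(tibble::as_tibble(cm, rownames = "sample_id"),
                     file.path(out_dir, sprintf("consensus_k%d.tsv", k)))
  }
  invisible(NULL)
}

stage_score <- function(config, state, out_dir) {
  bulk <- load_bulk(config, state, out_dir)
  sets <- read_gene_sets(file.path(out_dir, "bulk_score_sets.gmt"))
  mean_scores <- dplyr::bind_rows(lapply(
    c("liver", "repressed", "activatedT"),
    function(nm) {
      sc <- mean_signature_score(bulk$expression, sets[[nm]], name = nm)
      sc$score_name[sc$score_name == "repressed"] <- "immunosuppressed"
      sc
    }
  ))
  est <- estimate_like_scores(bulk$expression, sets$immune, sets$stromal,
                              alpha = config$score$alpha)
  state$bulk_scores <- dplyr::bind_rows(mean_scores, est)
  readr::write_tsv(state$bulk_scores, file.path(out_dir, "bulk_scores.tsv"))
  invisible(NULL)
}

stage_deg <- function(config, state, out_dir) {
  bulk <- load_bulk(config, state, out_dir)
  labels <- subtype_labels(state$subtyping)
  labels$cluster <- paste0("S", labels$cluster)
  sigs <- subtype_signatures(bulk$expression, labels,
                             fc_cut = config$deg$fc_cut, q_cut = config$deg$q_cut)
  state$bulk_signatures <- sigs
  readr::write_tsv(tidy(sigs), file.path(out_dir, "bulk_signatures.tsv"))
  readr::write_tsv(dplyr::bind_rows(sigs$contrasts),
                   file.path(out_dir, "bulk_deg.tsv"))
  invisible(NULL)
}

stage_panel <- function(config, state, out_dir) {
  sc <- load_sc(config, state, out_dir)
  bulk <- load_bulk(config, state, out_dir)
  sets <- read_gene_sets(file.path(out_dir, "score_sets.gmt"))
  pb <- pseudo_bulk(sc$expression, sc$cells)
  scores <- dplyr::bind_rows(
    mean_signature_score(pb, sets$liver, "liver"),
    mean_signature_score(pb, sets$repressed, "immunosuppressed"),
    mean_signature_score(pb, sets$activatedT, "activatedT")
  )
  ref_labels <- build_reference_labels(scores)
  sigs <- subtype_signatures(pb, ref_labels[, c("sample_id", "class")],
                             fc_cut = config$deg$fc_cut, q_cut = config$deg$q_cut)
  up <- lapply(sigs$signatures, `[[`, "up")
  clf <- panel_sweep(up, pb, ref_labels, n_min = config$panel$n_min,
                     n_max = config$panel$n_max, step = config$panel$step)
  state$classifier <- clf
  write_panel_classifier(clf, file.path(out_dir, "panel_classifier.json"))
  readr::write_tsv(ref_labels, file.path(out_dir, "reference_labels.tsv"))
  readr::write_tsv(clf$sweep, file.path(out_dir, "panel_sweep.tsv"))
  assignments <- classify_cohort(clf, bulk$expression,
                                 seed = derive_seed(config$seed, 4L))
  state$bulk_classes <- assignments
  readr::write_tsv(assignments, file.path(out_dir, "bulk_panel_classes.tsv"))
  invisible(NULL)
}

stage_enrich <- function(config, state, out_dir) {
  sc <- load_sc(config, state, out_dir)
  enr <- subtype_enrichment_score(sc$cells)
  readr::write_tsv(enr, file.path(out_dir, "enrichment_scores.tsv"))
  invisible(NULL)
}

stage_coexpr <- function(config, state, out_dir) {
  sc <- load_sc(config, state, out_dir)
  pc <- make_pseudocells(sc$expression, sc$cells,
                         size = config$coexpr$pseudocell_size,
                         seed = derive_seed(config$seed, 5L))
  beta <- pick_soft_threshold(pc$expression)
  mods <- detect_modules(pc$expression, beta$beta,
                         min_module_size = config$coexpr$min_module_size)
  mods <- module_trait_stats(mods, pc$traits, pc$expression,
                             mm_min = config$coexpr$mm_min,
                             gs_min = config$coexpr$gs_min)
  state$modules <- mods
  state$pseudocells <- pc
  readr::write_tsv(mods$modules, file.path(out_dir, "module_assignments.tsv"))
  readr::write_tsv(mods$module_trait, file.path(out_dir, "module_trait.tsv"))
  hub_sets <- lapply(mods$hubs, `[[`, "genes")
  hub_sets <- hub_sets[lengths(hub_sets) > 0]
  if (length(hub_sets) > 0) {
    write_gene_sets(hub_sets, file.path(out_dir, "module_hubs.gmt"))
  }
  invisible(NULL)
}

stage_regulon <- function(config, state, out_dir) {
  sc <- load_sc(config, state, out_dir)
  tfs <- readLines(file.path(out_dir, "tfs.txt"))
  regs <- infer_regulons(sc$expression, tfs, rho_min = config$regulon$rho_min,
                         min_targets = config$regulon$min_targets)
  state$regulons <- regs
  act <- aucell_scores(sc$expression, regs, top_frac = config$regulon$top_frac)
  readr::write_tsv(tidy(regs), file.path(out_dir, "regulons.tsv"))
  readr::write_tsv(act, file.path(out_dir, "regulon_activity.tsv"))
  if (!is.null(state$modules)) {
    target_trait <- config$regulon$hub_cell_type
    hub_mods <- Filter(function(h) h$trait == target_trait, state$modules$hubs)
    hubs <- unique(unlist(lapply(hub_mods, `[[`, "genes")))
    if (length(hubs) > 0) {
      sel <- hypergeom_tf_selection(hubs, regs, gene_ids(sc$expression),
                                    q_max = config$regulon$q_max)
      state$tf_selection <- sel
      readr::write_tsv(sel, file.path(out_dir, "tf_selection.tsv"))
    }
  }
  invisible(NULL)
}

stage_interact <- function(config, state, out_dir) {
  sc <- load_sc(config, state, out_dir)
  pairs <- readr::read_tsv(file.path(out_dir, "lr_pairs.tsv"),
                           show_col_types = FALSE)
  res <- permutation_test(sc$expression, sc$cells, pairs,
                          n_perm = config$interact$n_perm,
                          seed = derive_seed(config$seed, 6L),
                          min_frac = config$interact$min_frac)
  state$interactions <- res
  readr::write_tsv(res, file.path(out_dir, "interactions.tsv"))
  invisible(NULL)
}

stage_survival <- function(config, state, out_dir) {
  bulk <- load_bulk(config, state, out_dir)
  cls <- state$bulk_classes
  if (is.null(cls)) {
    labels <- subtype_labels(state$subtyping)
    cls <- tibble::tibble(sample_id = labels$sample_id,
                          class = paste0("S", labels$cluster))
    target <- names(sort(table(cls$class)))[1]
  } else {
    target <- config$survival$target_class
  }
  dat <- dplyr::inner_join(bulk$samples, cls, by = "sample_id")
  dat$group <- ifelse(dat$class == target, target, "rest")
  km <- km_estimate(dat)
  lr <- logrank_test(dat)
  readr::write_tsv(km, file.path(out_dir, "km_curves.tsv"))
  readr::write_tsv(lr, file.path(out_dir, "logrank.tsv"))
  state$logrank <- lr
  invisible(NULL)
}
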