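# The bulk <-> single-cell gene-panel classifier: pseudo-bulking, score-based
# reference labeling, a DEG-ranked panel sweep selecting the smallest panel
# with per-class FPR 0 and TPR 1 on the reference set, and application of the
# selected panel to fresh cohorts by NMF consensus clustering.

#' Pseudo-bulk a single-cell matrix per sample
#'
#' Each output column is the arithmetic mean over a sample's cells of every
#' gene's expression. Samples listed in `cells` with no cells in the matrix
#' are excluded with a warning.
#'
#' @param x Single-cell [expr_matrix()].
#' @param cells Cell annotation tibble (`cell_id`, `sample_id`).
#' @return An [expr_matrix()] with one column per sample.
#' @export
pseudo_bulk <- function(x, cells) {
  stopifnot(all(c("cell_id", "sample_id") %in% names(cells)))
  all_samples <- unique(cells$sample_id)
  cells <- cells[cells$cell_id %in% obs_ids(x), , drop = FALSE]
  samples <- all_samples[all_samples %in% cells$sample_id]
  if (length(samples) < length(all_samples)) {
    warning("sample(s) with zero cells excluded: ",
            paste(setdiff(all_samples, samples), collapse = ", "), call. = FALSE)
  }
  cols <- lapply(samples, function(s) {
    ids <- cells$cell_id[cells$sample_id == s]
    rowMeans(x[, ids, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- samples
  expr_matrix(out)
}

#' Reference class labels from signature scores
#'
#' Per score family, positives are defined by the upper-quartile rule
#' ([quartile_positive_labels()]). A sample positive for exactly one family
#' gets that family's class (liver -> cold, immunosuppressed -> suppressed,
#' activatedT -> hot); a sample positive for several families or none is
#' assigned the class of its maximal z-scored score.
#'
#' @param scores Long score tibble with `score_name` in `liver`,
#'   `immunosuppressed`, `activatedT` for every sample.
#' @return Tibble (`sample_id`, `class`, `n_positive`, `basis`) where `basis`
#'   records whether the quartile rule or the max-z tie-break decided.
#' @export
build_reference_labels <- function(scores) {
  families <- c(liver = "cold", immunosuppressed = "suppressed", activatedT = "hot")
  missing <- setdiff(names(families), unique(scores$score_name))
  if (length(missing) > 0) {
    stop("missing score(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  wide <- scores |>
    dplyr::filter(.data$score_name %in% names(families)) |>
    tidyr::pivot_wider(id_cols = "obs_id", names_from = "score_name",
                       values_from = "value")
  if (nrow(wide) < 4) stop("need >= 4 samples for quartile labeling", call. = FALSE)
  pos <- vapply(names(families), function(f) {
    lab <- quartile_positive_labels(scores, f)
    lab$positive[match(wide$obs_id, lab$obs_id)]
  }, logical(nrow(wide)))
  z <- vapply(names(families), function(f) {
    v <- wide[[f]]
    if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  }, numeric(nrow(wide)))
  n_pos <- rowSums(pos)
  class <- character(nrow(wide))
  basis <- character(nrow(wide))
  for (i in seq_len(nrow(wide))) {
    if (n_pos[i] == 1) {
      class[i] <- families[[names(families)[which(pos[i, ])]]]
      basis[i] <- "quartile"
    } else {
      class[i] <- families[[names(families)[which.max(z[i, ])]]]
      basis[i] <- "max_z"
    }
  }
  tibble::tibble(sample_id = wide$obs_id, class = class,
                 n_positive = as.integer(n_pos), basis = basis)
}

#' Panel sweep: smallest gene panel with perfect reference FPR/TPR
#'
#' For each panel size `n` from `n_min` to `n_max` in steps of `step`, the
#' panel is the union of the top `ceiling(n/3)` ranked signature genes of each
#' class. Reference samples are clustered by average-linkage hierarchical
#' clustering on correlation distance over the panel genes, cut into three
#' groups, and groups are mapped to classes by the best bijection against the
#' reference labels. Per-class one-vs-rest FPR and TPR are recorded; the
#' selected `n` is the smallest with all FPR = 0 and all TPR = 1. If no size
#' is perfect the classifier at the `n` maximizing mean TPR - mean FPR is
#' returned, flagged `perfect = FALSE`.
#'
#' @param signatures Named list (class -> ranked up-gene character vector);
#'   names must cover the reference classes.
#' @param ref Reference pseudo-bulk [expr_matrix()].
#' @param ref_labels Tibble (`sample_id`, `class`) from
#'   [build_reference_labels()].
#' @param n_min,n_max,step Sweep range and step over total panel size.
#' @return An object of class `panel_classifier`: `panel` (ordered genes),
#'   `panel_size`, `centroids` (genes x classes mean reference expression),
#'   `sweep` (tibble: `n`, `class`, `fpr`, `tpr`), `selected_n`, `perfect`.
#' @export
panel_sweep <- function(signatures, ref, ref_labels, n_min = 30L, n_max = 126L,
                        step = 3L) {
  classes <- sort(unique(ref_labels$class))
  missing <- setdiff(classes, names(signatures))
  if (length(missing) > 0) {
    stop("no signature for class(es): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(signatures[classes]) == 0)) {
    stop("empty signature for a reference class", call. = FALSE)
  }
  labels <- stats::setNames(ref_labels$class, ref_labels$sample_id)[obs_ids(ref)]
  sweep_rows <- list()
  for (n in seq(n_min, n_max, by = step)) {
    panel <- panel_genes(signatures, classes, n)
    pred <- cluster_panel(ref, panel, labels, classes)
    rates <- class_rates(pred, labels, classes)
    sweep_rows[[as.character(n)]] <- dplyr::mutate(rates, n = n, .before = 1)
  }
  sweep <- dplyr::bind_rows(sweep_rows)
  by_n <- sweep |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(perfect = all(.data$fpr == 0 & .data$tpr == 1),
                     util = mean(.data$tpr) - mean(.data$fpr))
  if (any(by_n$perfect)) {
    selected_n <- min(by_n$n[by_n$perfect])
    perfect <- TRUE
  } else {
    selected_n <- by_n$n[which.max(by_n$util)]
    perfect <- FALSE
    warning("no panel size achieves FPR 0 / TPR 1; returning best-utility size ",
            selected_n, call. = FALSE)
  }
  panel <- panel_genes(signatures, classes, selected_n)
  present <- intersect(panel, gene_ids(ref))
  centroids <- vapply(classes, function(cl) {
    rowMeans(ref[present, names(labels)[labels == cl], drop = FALSE])
  }, numeric(length(present)))
  structure(
    list(panel = panel, panel_size = length(panel), centroids = centroids,
         sweep = sweep, selected_n = selected_n, perfect = perfect,
         classes = classes, n_min = n_min, n_max = n_max, step = step),
    class = "panel_classifier"
  )
}

panel_genes <- function(signatures, classes, n) {
  top <- ceiling(n / length(classes))
  unique(unlist(lapply(classes, function(cl) head(signatures[[cl]], top)),
                use.names = FALSE))
}

# Hierarchical clustering of reference samples over the panel genes, cut into
# one group per class, mapped to classes by the best bijection.
cluster_panel <- function(ref, panel, labels, classes) {
  present <- intersect(panel, gene_ids(ref))
  sub <- ref[present, , drop = FALSE]
  d <- as.dist(1 - cor(as.matrix(unclass(sub))))
  tree <- hclust(d, method = "average")
  grp <- cutree(tree, k = length(classes))
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(seq_along(classes), classes))
  for (g in seq_along(classes)) {
    for (cl in classes) {
      counts[g, cl] <- sum(grp == g & labels == cl)
    }
  }
  perm <- best_assignment(counts)
  stats::setNames(classes[perm][grp], names(grp))
}

class_rates <- function(pred, labels, classes) {
  dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    tn <- sum(pred != cl & labels != cl)
    tibble::tibble(class = cl,
                   fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
                   tpr = if (tp + fn > 0) tp / (tp + fn) else 1)
  }))
}

#' Classify a cohort with a selected gene panel
#'
#' The cohort matrix is restricted to the panel genes (>= 50% of the panel
#' must be present), clustered by NMF consensus at `k = 3`, and each cluster
#' is mapped to the class whose reference centroid best correlates with the
#' cluster's mean profile (best bijection over the 3x3 correlation matrix).
#' The reported confidence is that correlation.
#'
#' @param clf A `panel_classifier`.
#' @param x Cohort [expr_matrix()] (log2-normalized).
#' @param n_runs,seed Consensus-clustering parameters.
#' @return Tibble (`sample_id`, `class`, `confidence`).
#' @export
classify_cohort <- function(clf, x, n_runs = 30L, seed = 1L) {
  stopifnot(inherits(clf, "panel_classifier"))
  present <- intersect(clf$panel, gene_ids(x))
  if (length(present) < 0.5 * length(clf$panel)) {
    stop("cohort covers < 50% of the panel; missing: ",
         paste(setdiff(clf$panel, present), collapse = ", "), call. = FALSE)
  }
  v <- shift_nonneg(x[present, , drop = FALSE])
  res <- consensus_cluster(v, k_range = 3L, n_runs = n_runs, seed = seed)
  lab <- res$per_k[["3"]]$labels
  shared <- intersect(present, rownames(clf$centroids))
  profiles <- vapply(sort(unique(lab)), function(g) {
    rowMeans(x[shared, names(lab)[lab == g], drop = FALSE])
  }, numeric(length(shared)))
  cors <- cor(profiles, clf$centroids[shared, , drop = FALSE])
  perm <- best_assignment(cors)
  cluster_class <- colnames(clf$centroids)[perm]
  conf <- cors[cbind(seq_len(nrow(cors)), perm)]
  tibble::tibble(
    sample_id = names(lab),
    class = cluster_class[lab],
    confidence = conf[lab]
  )
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat(sprintf("<panel_classifier> %d genes (sweep %d..%d, selected n = %d, %s)\n",
              x$panel_size, x$n_min, x$n_max, x$selected_n,
              if (x$perfect) "perfect FPR/TPR" else "non-perfect fallback"))
  invisible(x)
}

#' @method tidy panel_classifier
#' @export
tidy.panel_classifier <- function(x, ...) x$sweep

#' @method glance panel_classifier
#' @export
glance.panel_classifier <- function(x, ...) {
  at <- x$sweep[x$sweep$n == x$selected_n, ]
  tibble::tibble(
    panel_size = x$panel_size, selected_n = x$selected_n, perfect = x$perfect,
    max_fpr = max(at$fpr), min_tpr = min(at$tpr)
  )
}

#' Persist / restore a panel classifier as JSON
#'
#' @param clf A `panel_classifier`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `panel_classifier`.
#' @export
write_panel_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "panel_classifier"))
  payload <- list(
    panel = clf$panel, panel_size = clf$panel_size,
    centroids = list(genes = rownames(clf$centroids),
                     classes = colnames(clf$centroids),
                     values = unname(as.data.frame(clf$centroids))),
    sweep = clf$sweep, selected_n = clf$selected_n, perfect = clf$perfect,
    classes = clf$classes, n_min = clf$n_min, n_max = clf$n_max, step = clf$step
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel_classifier
#' @param path JSON file path.
#' @export
read_panel_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(as.data.frame(p$centroids$values))
  dimnames(centroids) <- list(p$centroids$genes, p$centroids$classes)
  structure(
    list(panel = p$panel, panel_size = p$panel_size, centroids = centroids,
         sweep = tibble::as_tibble(p$sweep), selected_n = p$selected_n,
         perfect = p$perfect, classes = p$classes, n_min = p$n_min,
         n_max = p$n_max, step = p$step),
    class = "panel_classifier"
  )
}
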