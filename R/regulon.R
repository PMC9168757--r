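# Regulon analysis: single-cell gene filtering on raw counts, lightweight
# correlation-based regulon inference, recovery-curve (AUCell-style) activity
# scores, and hypergeometric TF prioritization against hub genes.

#' Filter single-cell genes on raw counts
#'
#' Keeps genes whose total count is strictly greater than
#' `3 * 0.005 * n_cells` and which are detected (nonzero) in at least 0.5% of
#' cells.
#'
#' @param x A raw-count [expr_matrix()] (`is_counts = TRUE`).
#' @return Character vector of retained gene ids.
#' @export
filter_genes_sc <- function(x) {
  if (!is_counts(x)) stop("gene filtering requires a raw-count matrix", call. = FALSE)
  n_cells <- ncol(x)
  totals <- rowSums(x)
  detected <- rowSums(x > 0)
  keep <- totals > 3 * 0.005 * n_cells & detected >= 0.005 * n_cells
  gene_ids(x)[keep]
}

#' Infer regulons by rank correlation with transcription factors
#'
#' The targets of a TF are the genes (excluding the TF itself) whose Spearman
#' correlation with the TF is at least `rho_min`; regulons with fewer than
#' `min_targets` targets are discarded with a warning. The correlation is kept
#' as the association weight. With `detected_only = TRUE` (the default) the
#' rank correlation of a pair is computed over the cells in which both genes
#' are detected (nonzero): dropout zeros are missing observations, not
#' biology, and with typical dropout rates the all-cells rank correlation of
#' even a perfectly coupled TF-target pair is bounded well below common
#' thresholds by the independent zero masks alone.
#'
#' @param x Single-cell [expr_matrix()].
#' @param tf_list Character vector of TF gene ids.
#' @param rho_min Minimum Spearman correlation for a target.
#' @param min_targets Minimum regulon size retained.
#' @param detected_only Condition each pairwise correlation on joint detection.
#' @return Object of class `regulon_set`: named list `regulons` (per TF a
#'   tibble `target`, `weight`) plus the inference parameters.
#' @export
infer_regulons <- function(x, tf_list, rho_min = 0.3, min_targets = 10L,
                           detected_only = TRUE) {
  if (length(tf_list) == 0) stop("empty TF list", call. = FALSE)
  present <- intersect(tf_list, gene_ids(x))
  if (length(present) == 0) stop("no TF present in the matrix", call. = FALSE)
  if (length(present) < length(tf_list)) {
    warning("TF(s) absent from matrix dropped: ",
            paste(setdiff(tf_list, present), collapse = ", "), call. = FALSE)
  }
  xm <- as.matrix(unclass(x))
  if (detected_only) xm[xm == 0] <- NA
  rho <- suppressWarnings(
    cor(t(xm[present, , drop = FALSE]), t(xm), method = "spearman",
        use = "pairwise.complete.obs")
  )
  regulons <- list()
  for (tf in present) {
    r <- rho[tf, ]
    r[tf] <- NA
    hits <- which(!is.na(r) & r >= rho_min)
    if (length(hits) < min_targets) {
      warning("regulon '", tf, "' discarded (", length(hits), " targets < ",
              min_targets, ")", call. = FALSE)
      next
    }
    ord <- order(-r[hits])
    regulons[[tf]] <- tibble::tibble(
      target = names(hits)[ord], weight = unname(r[hits][ord])
    )
  }
  structure(list(regulons = regulons, rho_min = rho_min,
                 min_targets = min_targets),
            class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("<regulon_set> %d regulons (rho_min = %s, min_targets = %d)\n",
              length(x$regulons), format(x$rho_min), x$min_targets))
  invisible(x)
}

#' @method tidy regulon_set
#' @export
tidy.regulon_set <- function(x, ...) {
  dplyr::bind_rows(x$regulons, .id = "tf")
}

#' Regulon target genes
#'
#' @param x A `regulon_set`.
#' @param tf TF name.
#' @return Character vector of targets.
#' @export
regulon_targets <- function(x, tf) {
  stopifnot(inherits(x, "regulon_set"))
  x$regulons[[tf]]$target
}

#' Recovery-curve (AUC) regulon activity per cell
#'
#' Per cell, all genes are ranked by descending expression (ties broken by
#' ascending gene id); with `k = ceiling(top_frac * G)` the recovery curve
#' `h(i)` counts the regulon genes among the top `i` ranks, and the activity
#' is `sum_{i=1..k} h(i) / (k * m)` with `m` the number of regulon genes in
#' the matrix — the normalized area under the recovery curve, in `[0, 1]`.
#' Rank-based, hence invariant to monotone transforms of a cell's expression.
#'
#' @param x Single-cell [expr_matrix()].
#' @param regulons A `regulon_set`, or a named list of target-gene vectors.
#' @param top_frac Fraction of top-ranked genes integrated over.
#' @return Long tibble (`cell_id`, `regulon`, `auc`).
#' @export
aucell_scores <- function(x, regulons, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac < 1)
  sets <- if (inherits(regulons, "regulon_set")) {
    lapply(regulons$regulons, `[[`, "target")
  } else {
    regulons
  }
  ids <- gene_ids(x)
  g <- length(ids)
  k <- ceiling(top_frac * g)
  set_idx <- lapply(names(sets), function(nm) {
    idx <- match(intersect(sets[[nm]], ids), ids)
    if (length(idx) == 0) {
      warning("regulon '", nm, "' has no genes in the matrix; zero scores",
              call. = FALSE)
    }
    idx
  })
  names(set_idx) <- names(sets)
  n_obs <- ncol(x)
  out <- matrix(0, n_obs, length(sets),
                dimnames = list(obs_ids(x), names(sets)))
  ranks <- integer(g)
  for (j in seq_len(n_obs)) {
    ord <- order(-x[, j], ids)
    ranks[ord] <- seq_len(g)
    for (s in seq_along(set_idx)) {
      idx <- set_idx[[s]]
      if (length(idx) == 0) next
      rr <- ranks[idx]
      out[j, s] <- sum(pmax(k - rr + 1, 0)) / (k * length(idx))
    }
  }
  tibble::tibble(
    cell_id = rep(rownames(out), times = ncol(out)),
    regulon = rep(colnames(out), each = nrow(out)),
    auc = as.vector(out)
  )
}

#' Hypergeometric TF prioritization against hub genes
#'
#' For each regulon, with `N = |universe|`, `K = |targets in universe|`,
#' `n = |hubs|` and `x = |targets in hubs|`, the enrichment p-value is
#' `P(X >= x)` under Hypergeometric(N, K, n), BH-adjusted across TFs;
#' a TF is selected when `q < q_max`.
#'
#' @param hubs Character vector of hub genes (must lie in `universe`).
#' @param regulons A `regulon_set` or named list of target vectors.
#' @param universe Character vector: the gene universe.
#' @param q_max Selection threshold on the BH-adjusted p.
#' @return Tibble (`tf`, `n_targets`, `overlap`, `p`, `q`, `selected`).
#' @export
hypergeom_tf_selection <- function(hubs, regulons, universe, q_max = 0.05) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(hubs %in% universe)) {
    stop("hub genes outside the universe: ",
         paste(setdiff(hubs, universe), collapse = ", "), call. = FALSE)
  }
  sets <- if (inherits(regulons, "regulon_set")) {
    lapply(regulons$regulons, `[[`, "target")
  } else {
    regulons
  }
  big_n <- length(unique(universe))
  n_hub <- length(unique(hubs))
  rows <- dplyr::bind_rows(lapply(names(sets), function(tf) {
    targets <- intersect(sets[[tf]], universe)
    x_ov <- length(intersect(targets, hubs))
    tibble::tibble(
      tf = tf, n_targets = length(targets), overlap = x_ov,
      p = phyper(x_ov - 1, length(targets), big_n - length(targets), n_hub,
                 lower.tail = FALSE)
    )
  }))
  rows$q <- bh_adjust(rows$p)
  rows$selected <- rows$q < q_max
  rows
}
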