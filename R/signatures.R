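# Signature scoring: mean marker scores, single-sample rank-based gene-set
# enrichment (ssGSEA-style), immune/stromal/purity scores, quartile positive
# labeling, and the observed/expected subtype-per-cluster enrichment ratio.

score_table <- function(obs, name, values) {
  tibble::tibble(obs_id = obs, score_name = name, value = unname(values))
}

match_set <- function(x, genes, set_name) {
  present <- intersect(genes, gene_ids(x))
  if (length(present) == 0) {
    stop("gene set '", set_name, "' has no genes in the matrix", call. = FALSE)
  }
  if (length(present) < length(unique(genes))) {
    warning(sprintf("gene set '%s': %d of %d genes absent from matrix",
                    set_name, length(unique(genes)) - length(present),
                    length(unique(genes))), call. = FALSE)
  }
  present
}

#' Mean signature score
#'
#' Per observation, the average log2 expression over the gene set's genes
#' present in the matrix (the convention behind the liver / immunosuppressed /
#' activated-T scores: e.g. the liver score is the average of 24 liver marker
#' genes).
#'
#' @param x An [expr_matrix()].
#' @param genes Character vector: the gene set.
#' @param name Score name recorded in the output.
#' @return Long tibble (`obs_id`, `score_name`, `value`).
#' @export
mean_signature_score <- function(x, genes, name = "signature") {
  present <- match_set(x, genes, name)
  score_table(obs_ids(x), name, colMeans(x[present, , drop = FALSE]))
}

#' Single-sample rank-based gene-set enrichment score
#'
#' For each observation, genes are ranked by descending expression (ties
#' broken by ascending gene id) and a weighted Kolmogorov-Smirnov walk is
#' taken down the list: in-set genes advance the in-set CDF by their rank
#' weight `(G - position + 1)^alpha` (normalized to sum 1), out-of-set genes
#' advance the out-of-set CDF by `1/(G - m)`. The score is the sum over all
#' positions of `CDF_in - CDF_out`. Rank-based, hence invariant to any
#' strictly monotone per-observation transform of expression.
#'
#' @inheritParams mean_signature_score
#' @param alpha Rank-weight exponent (0 gives the unweighted KS walk).
#' @return Long tibble (`obs_id`, `score_name`, `value`).
#' @export
ssgsea_score <- function(x, genes, alpha = 0.25, name = "ssgsea") {
  present <- match_set(x, genes, name)
  g <- nrow(x)
  m <- length(present)
  if (m >= g) stop("gene set '", name, "' covers all genes in the matrix", call. = FALSE)
  ids <- gene_ids(x)
  in_set <- ids %in% present
  scores <- vapply(seq_len(ncol(x)), function(j) {
    ord <- order(-x[, j], ids)
    hit <- in_set[ord]
    w <- (g - seq_len(g) + 1)^alpha
    cdf_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    cdf_out <- cumsum(!hit) / (g - m)
    sum(cdf_in - cdf_out)
  }, numeric(1))
  score_table(obs_ids(x), name, scores)
}

#' Immune, stromal, combined and purity scores
#'
#' Immune and stromal scores are [ssgsea_score()] values on user-supplied
#' immune and stromal gene sets; the combined score is their sum, and tumor
#' purity is an affine-cosine transform `cos(a + b * combined)` of the
#' combined score. The default transform constants are those published with
#' the ESTIMATE method; they are configurable and carry no meaning for data
#' on other scales beyond being strictly decreasing in the combined score
#' over the valid domain `a + b * combined` in `(0, pi)`.
#'
#' @param x An [expr_matrix()].
#' @param immune_genes,stromal_genes Character vectors of set genes.
#' @param alpha Rank-weight exponent for the enrichment walk.
#' @param purity_a,purity_b Purity transform constants.
#' @return Long tibble with scores `immune`, `stromal`, `combined`, `purity`.
#' @export
estimate_like_scores <- function(x, immune_genes, stromal_genes, alpha = 0.25,
                                 purity_a = 0.6049872018, purity_b = 0.0001467884) {
  imm <- ssgsea_score(x, immune_genes, alpha = alpha, name = "immune")
  str <- ssgsea_score(x, stromal_genes, alpha = alpha, name = "stromal")
  combined <- imm$value + str$value
  dplyr::bind_rows(
    imm, str,
    score_table(obs_ids(x), "combined", combined),
    score_table(obs_ids(x), "purity", purity_transform(combined, purity_a, purity_b))
  )
}

#' @rdname estimate_like_scores
#' @param combined Combined immune + stromal score.
#' @export
purity_transform <- function(combined, purity_a = 0.6049872018,
                             purity_b = 0.0001467884) {
  cos(purity_a + purity_b * combined)
}

#' Upper-quartile positive labeling
#'
#' The cutoff is the 75th percentile of the score (linear interpolation
#' between closest ranks); observations at or above the cutoff are positive.
#'
#' @param scores Long score tibble (`obs_id`, `score_name`, `value`).
#' @param score_name Which score to threshold.
#' @return Tibble (`obs_id`, `positive`, `cutoff`).
#' @export
quartile_positive_labels <- function(scores, score_name) {
  sub <- scores[scores$score_name == score_name, ]
  if (nrow(sub) < 4) stop("need >= 4 observations for a quartile cutoff", call. = FALSE)
  if (length(unique(sub$value)) == 1) {
    warning("all '", score_name, "' values identical; every observation positive",
            call. = FALSE)
  }
  cutoff <- unname(quantile(sub$value, 0.75, type = 7))
  tibble::tibble(obs_id = sub$obs_id, positive = sub$value >= cutoff, cutoff = cutoff)
}

#' Observed/expected subtype enrichment per cell cluster
#'
#' For sample group g and cell cluster (type) c, the enrichment ratio is
#' `[n(g,c)/n(g)] / [n(c)/N]`: the within-group frequency of the cluster
#' divided by the cluster's overall frequency. A ratio above 1 means the
#' cluster is over-represented in the group. For each group the
#' cluster-frequency-weighted ratios sum to 1 (mass conservation).
#'
#' @param cells Tibble with `cell_type` and `group_label` per cell (see
#'   [read_annotation()]); `group_label` may instead be supplied via
#'   `group_of_sample`.
#' @param group_of_sample Optional named vector mapping `sample_id` to group.
#' @return Tibble (`group`, `cell_type`, `n_cells`, `ratio`).
#' @export
subtype_enrichment_score <- function(cells, group_of_sample = NULL) {
  if (nrow(cells) == 0) stop("empty cell table", call. = FALSE)
  if (!is.null(group_of_sample)) {
    cells$group_label <- unname(group_of_sample[cells$sample_id])
  }
  if (!all(c("cell_type", "group_label") %in% names(cells)) ||
      anyNA(cells$group_label)) {
    stop("every cell needs a `cell_type` and a `group_label`", call. = FALSE)
  }
  n_total <- nrow(cells)
  counts <- cells |>
    dplyr::count(.data$group_label, .data$cell_type, name = "n_cells") |>
    tidyr::complete(.data$group_label, .data$cell_type,
                    fill = list(n_cells = 0L))
  group_n <- cells |> dplyr::count(.data$group_label, name = "n_group")
  type_n <- cells |> dplyr::count(.data$cell_type, name = "n_type")
  counts |>
    dplyr::left_join(group_n, by = "group_label") |>
    dplyr::left_join(type_n, by = "cell_type") |>
    dplyr::mutate(
      ratio = (.data$n_cells / .data$n_group) / (.data$n_type / n_total)
    ) |>
    dplyr::select(group = "group_label", cell_type = "cell_type",
                  n_cells = "n_cells", ratio = "ratio")
  }
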