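# Ligand-receptor interaction screening between annotated cell types with an
# empirical permutation null: the score of a pair for ordered sender/receiver
# types is the mean of the ligand's sender-type mean and the receptor's
# receiver-type mean, and significance comes from re-scoring under random
# permutations of the cell-type labels.

#' Ligand-receptor scores between cell-type pairs
#'
#' For each pair and each ordered type pair (A, B), the score is
#' `(mean ligand over A-cells + mean receptor over B-cells) / 2`, computed
#' only when the ligand is nonzero in at least `min_frac` of A-cells and the
#' receptor in at least `min_frac` of B-cells; filtered combinations keep
#' `passed_filter = FALSE` and an `NA` score. Pairs naming genes absent from
#' the matrix are skipped with a warning.
#'
#' @param x Single-cell [expr_matrix()].
#' @param cells Cell annotation tibble (`cell_id`, `cell_type`).
#' @param pairs Tibble (`pair_id`, `ligand`, `receptor`) with unique pair ids.
#' @param min_frac Minimum expressed fraction in the sender / receiver type.
#' @return Tibble (`pair_id`, `ligand`, `receptor`, `type_a`, `type_b`,
#'   `expressed_frac_l`, `expressed_frac_r`, `passed_filter`, `score`).
#' @export
lr_scores <- function(x, cells, pairs, min_frac = 0.1) {
  stopifnot(all(c("pair_id", "ligand", "receptor") %in% names(pairs)))
  if (anyDuplicated(pairs$pair_id)) stop("duplicate pair_id", call. = FALSE)
  known <- pairs$ligand %in% gene_ids(x) & pairs$receptor %in% gene_ids(x)
  if (any(!known)) {
    warning("pair(s) with unknown gene skipped: ",
            paste(pairs$pair_id[!known], collapse = ", "), call. = FALSE)
    pairs <- pairs[known, , drop = FALSE]
  }
  labels <- type_labels(cells, x)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  stats <- type_stats(x, genes, labels)
  grid <- expand.grid(type_a = stats$types, type_b = stats$types,
                      stringsAsFactors = FALSE)
  out <- tidyr::crossing(pairs[, c("pair_id", "ligand", "receptor")], grid)
  out$expressed_frac_l <- stats$frac[cbind(out$ligand, out$type_a)]
  out$expressed_frac_r <- stats$frac[cbind(out$receptor, out$type_b)]
  out$passed_filter <- out$expressed_frac_l >= min_frac &
    out$expressed_frac_r >= min_frac
  out$score <- ifelse(
    out$passed_filter,
    (stats$mean[cbind(out$ligand, out$type_a)] +
       stats$mean[cbind(out$receptor, out$type_b)]) / 2,
    NA_real_
  )
  tibble::as_tibble(out)
}

type_labels <- function(cells, x) {
  stopifnot(all(c("cell_id", "cell_type") %in% names(cells)))
  labels <- cells$cell_type[match(obs_ids(x), cells$cell_id)]
  if (anyNA(labels)) stop("cells in the matrix lack annotations", call. = FALSE)
  labels
}

type_stats <- function(x, genes, labels) {
  types <- sort(unique(labels))
  xm <- as.matrix(unclass(x[genes, , drop = FALSE]))
  counts <- as.vector(table(factor(labels, levels = types)))
  sums <- t(rowsum(t(xm), group = factor(labels, levels = types)))
  nnz <- t(rowsum(t(xm > 0) * 1, group = factor(labels, levels = types)))
  means <- sweep(sums, 2, counts, "/")
  frac <- sweep(nnz, 2, counts, "/")
  dimnames(means) <- dimnames(frac) <- list(genes, types)
  list(types = types, counts = stats::setNames(counts, types),
       mean = means, frac = frac)
}

#' Permutation test for ligand-receptor interactions
#'
#' The null distribution of each (pair, sender, receiver) score is obtained by
#' re-scoring after jointly permuting the cell-type labels across all cells
#' (type sizes preserved, expression fixed), `n_perm` times with a seeded
#' generator. The one-sided p is `(1 + #\{null >= observed\}) / (n_perm + 1)`,
#' so the minimum attainable p is `1 / (n_perm + 1)`. Types with fewer than 3
#' cells are flagged `low_power`.
#'
#' @inheritParams lr_scores
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed.
#' @return The [lr_scores()] tibble with `p` (NA for filtered combinations)
#'   and `low_power` columns appended.
#' @export
permutation_test <- function(x, cells, pairs, n_perm = 1000L, seed = 1L,
                             min_frac = 0.1) {
  stopifnot(n_perm >= 100)
  obs <- lr_scores(x, cells, pairs, min_frac = min_frac)
  if (nrow(obs) == 0) return(obs)
  labels <- type_labels(cells, x)
  types <- sort(unique(labels))
  genes <- unique(c(obs$ligand, obs$receptor))
  xm <- as.matrix(unclass(x[genes, , drop = FALSE]))
  counts <- as.vector(table(factor(labels, levels = types)))

  lig_idx <- cbind(match(obs$ligand, genes), match(obs$type_a, types))
  rec_idx <- cbind(match(obs$receptor, genes), match(obs$type_b, types))
  flat_l <- (lig_idx[, 2] - 1) * length(genes) + lig_idx[, 1]
  flat_r <- (rec_idx[, 2] - 1) * length(genes) + rec_idx[, 1]

  set.seed(derive_seed(seed, 777L))
  exceed <- integer(nrow(obs))
  fl <- factor(labels, levels = types)
  for (b in seq_len(n_perm)) {
    perm <- sample(fl)
    sums <- t(rowsum(t(xm), group = perm))
    means <- sweep(sums, 2, counts, "/")
    null_score <- (means[flat_l] + means[flat_r]) / 2
    exceed <- exceed + (null_score >= obs$score)
  }
  obs$p <- ifelse(obs$passed_filter, (1 + exceed) / (n_perm + 1), NA_real_)
  low <- types[counts < 3]
  obs$low_power <- obs$type_a %in% low | obs$type_b %in% low
  obs
}
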