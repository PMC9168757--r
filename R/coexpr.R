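# Weighted co-expression analysis on pseudocells: soft-threshold selection by
# scale-free fit, topological-overlap modules from a fixed-height tree cut,
# module eigengenes, module-trait statistics, and hub-gene calling by joint
# module-membership / gene-significance thresholds.

#' Aggregate cells into pseudocells within cell types
#'
#' Within each cell type, cells are randomly partitioned (seeded) into groups
#' of `size`; a remainder group is kept as its own pseudocell when larger than
#' `size/2` and merged into the last full group otherwise. Types with fewer
#' than `size` cells form a single pseudocell with a warning. Each pseudocell
#' is the per-gene mean of its cells.
#'
#' @param x Single-cell [expr_matrix()].
#' @param cells Cell annotation tibble (`cell_id`, `cell_type`).
#' @param size Cells per pseudocell.
#' @param seed Integer seed for the partition.
#' @return List with `expression` (pseudocell [expr_matrix()]) and `traits`
#'   (tibble: `pseudocell_id`, `cell_type`).
#' @export
make_pseudocells <- function(x, cells, size = 10L, seed = 1L) {
  if (nrow(cells) == 0) stop("empty cell annotation", call. = FALSE)
  stopifnot(all(c("cell_id", "cell_type") %in% names(cells)))
  cells <- cells[cells$cell_id %in% obs_ids(x), , drop = FALSE]
  set.seed(seed)
  cols <- list()
  types <- character(0)
  for (ty in unique(cells$cell_type)) {
    ids <- sample(cells$cell_id[cells$cell_type == ty])
    if (length(ids) < size) {
      warning("cell type '", ty, "' has fewer than ", size,
              " cells; kept as a single pseudocell", call. = FALSE)
      groups <- list(ids)
    } else {
      n_full <- floor(length(ids) / size)
      groups <- split(ids[seq_len(n_full * size)],
                      rep(seq_len(n_full), each = size))
      rem <- ids[-seq_len(n_full * size)]
      if (length(rem) > size / 2) {
        groups[[length(groups) + 1]] <- rem
      } else if (length(rem) > 0) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], rem)
      }
    }
    for (i in seq_along(groups)) {
      cols[[paste0(ty, "_", i)]] <- rowMeans(x[, groups[[i]], drop = FALSE])
      types <- c(types, ty)
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  list(
    expression = expr_matrix(out),
    traits = tibble::tibble(pseudocell_id = names(cols), cell_type = types)
  )
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, the adjacency is `|cor|^beta` (unsigned network);
#' connectivity is the row sum excluding self. The scale-free fit R^2 is the
#' squared correlation between `log10(frequency)` and `log10(mean
#' connectivity)` over bins equal-width in log-connectivity. The selected
#' power is the smallest reaching `r2_target`, otherwise `default_power` with
#' a warning.
#'
#' @param x Pseudocell [expr_matrix()] (genes x pseudocells).
#' @param powers Candidate integer powers.
#' @param r2_target Scale-free fit threshold.
#' @param n_bins Number of connectivity bins.
#' @param default_power Power used when no candidate reaches `r2_target` —
#'   strongly modular networks have bimodal connectivity and are not
#'   scale-free, in which case the conventional unsigned-network default (6)
#'   is a better choice than the argmax of noise-level fit values.
#' @return List of class `soft_threshold_fit` with `beta` and `fit`
#'   (tibble: `power`, `r2`, `mean_connectivity`).
#' @export
pick_soft_threshold <- function(x, powers = 1:20, r2_target = 0.8, n_bins = 10L,
                                default_power = 6L) {
  if (nrow(x) < 20) stop("need >= 20 genes", call. = FALSE)
  cmat <- abs(gene_cor(x))
  diag(cmat) <- 0
  rows <- lapply(powers, function(b) {
    a <- cmat^b
    k <- rowSums(a)
    tibble::tibble(power = b, r2 = scale_free_r2(k, n_bins),
                   mean_connectivity = mean(k))
  })
  fit <- dplyr::bind_rows(rows)
  ok <- which(fit$r2 >= r2_target)
  if (length(ok) > 0) {
    beta <- fit$power[ok[1]]
  } else {
    # Strongly modular networks are not scale-free (bimodal connectivity), so
    # no power reaches the target; fall back to the canonical unsigned-network
    # default rather than the argmax of noise-level fit values.
    beta <- default_power
    warning("no power reaches R^2 >= ", r2_target,
            "; falling back to the default power ", beta, call. = FALSE)
  }
  structure(list(beta = beta, fit = fit), class = "soft_threshold_fit")
}

# Correlation over pseudocells with constant genes removed (warned).
gene_cor <- function(x) {
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) removed before correlation",
            call. = FALSE)
    x <- x[sds > 0, , drop = FALSE]
  }
  cor(t(as.matrix(unclass(x))))
}

# Scale-free fit: frequency vs mean connectivity over bins equal-width in
# log10(k), R^2 of the log-log regression.
scale_free_r2 <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(0)
  lk <- log10(k)
  bins <- cut(lk, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(0)
  suppressWarnings(cor(log10(freq[keep]), log10(mk[keep]))^2)
}

#' Detect co-expression modules from the topological overlap matrix
#'
#' Adjacency `a_ij = |cor|^beta`; topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`;
#' average-linkage clustering of `1 - TOM` with a fixed cut at `cut_height`
#' of the min-max-normalized merge-height range (modules assemble low in the
#' tree; the uncorrelated background joins near the top, so the cut sits well
#' below it). Branches of at least `min_module_size`
#' genes become modules (numbered by decreasing size); smaller branches go to
#' module 0 (unassigned). The module eigengene is the first principal
#' component of the module's standardized gene submatrix, sign-oriented to
#' correlate positively with the module's mean expression profile, scaled to
#' unit variance.
#'
#' @param x Pseudocell [expr_matrix()].
#' @param beta Soft-threshold power (>= 1).
#' @param min_module_size Minimum genes per module.
#' @param cut_height Fixed cut as a fraction of the normalized merge-height
#'   range.
#' @return Object of class `module_result`: `modules` (tibble: `gene`,
#'   `module`), `eigengenes` (modules x pseudocells matrix), `beta`; completed
#'   by [module_trait_stats()].
#' @export
detect_modules <- function(x, beta, min_module_size = 20L, cut_height = 0.8) {
  stopifnot(beta >= 1)
  cmat <- gene_cor(x)
  genes <- rownames(cmat)
  x <- x[genes, , drop = FALSE]
  if (length(genes) < min_module_size) {
    modules <- tibble::tibble(gene = gene_ids(x), module = 0L)
    return(structure(list(modules = modules,
                          eigengenes = matrix(0, 0, ncol(x),
                                              dimnames = list(NULL, obs_ids(x))),
                          beta = beta, cut_height = cut_height,
                          min_module_size = min_module_size),
                     class = "module_result"))
  }
  tom <- tom_matrix(abs(cmat)^beta)
  tree <- hclust(as.dist(1 - tom), method = "average")
  # fixed cut on the min-max-normalized merge heights: low enough to separate
  # modules (which assemble early) from the noise background joining near the
  # top of the tree
  h_rel <- min(tree$height) + cut_height * diff(range(tree$height))
  grp <- cutree(tree, h = h_rel)
  sizes <- sort(table(grp), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- integer(length(genes))
  for (i in seq_along(keep)) module[grp == as.integer(keep[i])] <- i
  modules <- tibble::tibble(gene = genes, module = module)
  egs <- lapply(seq_along(keep), function(m) {
    module_eigengene(x[genes[module == m], , drop = FALSE])
  })
  eigengenes <- do.call(rbind, egs)
  if (is.null(eigengenes)) {
    eigengenes <- matrix(0, 0, ncol(x), dimnames = list(NULL, obs_ids(x)))
  } else {
    dimnames(eigengenes) <- list(paste0("M", seq_along(keep)), obs_ids(x))
  }
  structure(
    list(modules = modules, eigengenes = eigengenes, beta = beta,
         cut_height = cut_height, min_module_size = min_module_size),
    class = "module_result"
  )
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' self-adjacency excluded and `TOM_ii = 1` by convention.
#'
#' @param a Symmetric adjacency matrix with entries in `[0, 1]`.
#' @return Symmetric TOM with unit diagonal.
#' @export
tom_matrix <- function(a) {
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

module_eigengene <- function(xm) {
  z <- t(scale(t(as.matrix(unclass(xm)))))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (sd(v) > 0) v <- v / sd(v)
  if (suppressWarnings(isTRUE(cor(v, colMeans(xm)) < 0))) v <- -v
  v
}

#' Module-trait statistics, module membership and hub genes
#'
#' Pearson correlation (and two-sided p with n-2 df) between each module
#' eigengene and each one-hot cell-type indicator; module membership (MM) is
#' each gene's absolute correlation with its own module's eigengene; gene
#' significance (GS) its absolute correlation with each trait indicator. Hub
#' genes of a module satisfy `MM > mm_min` and `GS > gs_min` for the module's
#' maximal-|r| trait (defaults 0.7 / 0.6).
#'
#' @param result A `module_result` from [detect_modules()].
#' @param traits Tibble (`pseudocell_id`, `cell_type`) aligned with the
#'   pseudocell matrix.
#' @param x The pseudocell [expr_matrix()] used for module detection.
#' @param mm_min,gs_min Hub thresholds.
#' @return The completed `module_result` with `module_trait` (tibble:
#'   `module`, `trait`, `r`, `p`), `mm` (tibble: `gene`, `module`, `mm`),
#'   `gs` (long tibble: `gene`, `trait`, `gs`) and `hubs` (named list).
#' @export
module_trait_stats <- function(result, traits, x, mm_min = 0.7, gs_min = 0.6) {
  stopifnot(inherits(result, "module_result"))
  pc_ids <- colnames(result$eigengenes)
  if (nrow(result$eigengenes) == 0) stop("no modules to score", call. = FALSE)
  stopifnot(setequal(traits$pseudocell_id, pc_ids))
  types <- sort(unique(traits$cell_type))
  onehot <- vapply(types, function(ty) {
    as.numeric(traits$cell_type[match(pc_ids, traits$pseudocell_id)] == ty)
  }, numeric(length(pc_ids)))
  const <- apply(onehot, 2, sd) == 0
  if (any(const)) {
    warning("constant trait(s) recorded with r = 0: ",
            paste(types[const], collapse = ", "), call. = FALSE)
  }
  n <- length(pc_ids)
  r_mat <- suppressWarnings(cor(t(result$eigengenes), onehot))
  r_mat[!is.finite(r_mat)] <- 0
  module_trait <- tibble::tibble(
    module = rep(seq_len(nrow(r_mat)), times = ncol(r_mat)),
    trait = rep(types, each = nrow(r_mat)),
    r = as.vector(r_mat),
    p = as.vector(cor_pvalue(r_mat, n))
  )
  xs <- as.matrix(unclass(x[result$modules$gene, pc_ids, drop = FALSE]))
  gs_mat <- suppressWarnings(abs(cor(t(xs), onehot)))
  gs_mat[!is.finite(gs_mat)] <- 0
  gs <- tibble::tibble(
    gene = rep(result$modules$gene, times = ncol(gs_mat)),
    trait = rep(types, each = nrow(gs_mat)),
    gs = as.vector(gs_mat)
  )
  mm_val <- rep(NA_real_, nrow(result$modules))
  for (m in seq_len(nrow(result$eigengenes))) {
    idx <- which(result$modules$module == m)
    if (length(idx) > 0) {
      mm_val[idx] <- suppressWarnings(
        abs(cor(t(xs[idx, , drop = FALSE]), result$eigengenes[m, ]))
      )
    }
  }
  mm <- tibble::tibble(gene = result$modules$gene,
                       module = result$modules$module, mm = mm_val)
  hubs <- list()
  for (m in seq_len(nrow(result$eigengenes))) {
    best_trait <- types[which.max(abs(r_mat[m, ]))]
    in_mod <- result$modules$module == m
    ok <- in_mod & !is.na(mm_val) & mm_val > mm_min &
      gs_mat[, best_trait] > gs_min
    hubs[[paste0("M", m)]] <- list(
      trait = best_trait,
      genes = result$modules$gene[ok]
    )
  }
  result$module_trait <- module_trait
  result$mm <- mm
  result$gs <- gs
  result$hubs <- hubs
  result$mm_min <- mm_min
  result$gs_min <- gs_min
  result
}

#' @export
print.module_result <- function(x, ...) {
  n_mod <- nrow(x$eigengenes)
  cat(sprintf("<module_result> %d modules over %d genes (beta = %s)\n",
              n_mod, nrow(x$modules), format(x$beta)))
  invisible(x)
}

#' @method tidy module_result
#' @export
tidy.module_result <- function(x, ...) {
  if (!is.null(x$module_trait)) x$module_trait else x$modules
}

#' @method glance module_result
#' @export
glance.module_result <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$eigengenes),
    n_genes = nrow(x$modules),
    n_unassigned = sum(x$modules$module == 0),
    beta = x$beta
  )
}
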