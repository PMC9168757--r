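# NMF consensus subtyping: variance-based gene filtering, multiplicative-
# update factorization, consensus clustering across seeded restarts, and
# cophenetic-drop rank selection.

#' Filter genes by mean absolute deviation
#'
#' Keeps genes whose mean absolute deviation about the gene mean,
#' `(1/n) * sum_s |x_gs - mean_g|`, exceeds `threshold`. Alternatively the top
#' `top_n` genes ranked by that deviation can be requested, for cohorts on a
#' different dispersion scale.
#'
#' @param x An [expr_matrix()].
#' @param threshold Deviation threshold (log2 units); genes strictly above it
#'   are kept.
#' @param top_n If non-`NULL`, ignore `threshold` and keep the `top_n` genes
#'   with the largest deviation instead.
#' @return Character vector of retained gene ids, input order preserved.
#' @export
mad_filter <- function(x, threshold = 1.0, top_n = NULL) {
  stopifnot(nrow(x) > 0, ncol(x) > 0)
  dev <- rowMeans(abs(x - rowMeans(x)))
  if (!is.null(top_n)) {
    stopifnot(top_n >= 1)
    keep <- rank(-dev, ties.method = "first") <= top_n
  } else {
    keep <- dev > threshold
  }
  if (!any(keep)) {
    stop("no genes pass the deviation filter; lower `threshold`", call. = FALSE)
  }
  gene_ids(x)[keep]
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss `||V - WH||_F` with the standard
#' multiplicative updates, stopping when the relative loss change falls below
#' `tol`. `W` and `H` are initialized Uniform(0,1) scaled so the product's
#' expected magnitude matches `mean(V)`.
#'
#' @param v Non-negative numeric matrix (use [shift_nonneg()] on log-scale
#'   data first).
#' @param k Factorization rank, `1 <= k < min(dim(v))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum update iterations.
#' @param tol Relative loss-change stopping tolerance.
#' @return List with `w` (genes x k), `h` (k x samples), `rel_error`
#'   (`||V - WH||_F / ||V||_F`), `loss` (per-iteration loss trajectory) and
#'   `n_iter`.
#' @export
nmf_factorize <- function(v, k, seed = 1L, max_iter = 2000L, tol = 1e-5) {
  v <- as.matrix(unclass(v))
  if (any(v < 0)) {
    stop("NMF input has negative entries; apply shift_nonneg() first", call. = FALSE)
  }
  if (k < 1 || k >= min(dim(v))) {
    stop("rank k must satisfy 1 <= k < min(dim(v))", call. = FALSE)
  }
  set.seed(seed)
  scale <- sqrt(max(mean(v), .Machine$double.eps) / k)
  w0 <- matrix(runif(nrow(v) * k), nrow(v), k) * 2 * scale
  h0 <- matrix(runif(k * ncol(v)), k, ncol(v)) * 2 * scale
  fit <- nmf_mu_cpp(v, w0, h0, as.integer(max_iter), tol)
  dimnames(fit$W) <- list(rownames(v), NULL)
  dimnames(fit$H) <- list(NULL, colnames(v))
  list(w = fit$W, h = fit$H, rel_error = fit$rel_error,
       loss = fit$loss, n_iter = fit$n_iter)
}

#' Consensus clustering over NMF restarts
#'
#' For each candidate rank `k`, runs `n_runs` seeded NMF restarts, assigns
#' each sample to its argmax component of `H`, and averages the per-run
#' co-clustering connectivity matrices into a consensus matrix `C(k)`.
#' Degenerate runs (all samples on one component) are excluded with a warning.
#' The cophenetic coefficient is the Pearson correlation between the
#' consensus dissimilarity `1 - C` and the cophenetic distances of its
#' average-linkage tree; labels come from cutting that tree into `k` groups.
#'
#' @param v Non-negative matrix (genes x samples).
#' @param k_range Integer vector of candidate ranks.
#' @param n_runs Restarts per rank (>= 2).
#' @param seed Master seed; per-run sub-seeds are derived by fixed offsets.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `subtyping_result`: list with `k_range`, `per_k` (per rank:
#'   `consensus`, `cophenetic`, `labels`, `n_runs_used`), and `k_selected`
#'   (filled by [select_k()] when `length(k_range) >= 3`).
#' @export
consensus_cluster <- function(v, k_range, n_runs = 30L, seed = 1L,
                              max_iter = 2000L, tol = 1e-5) {
  stopifnot(n_runs >= 2)
  v <- as.matrix(unclass(v))
  n <- ncol(v)
  samples <- colnames(v)
  per_k <- list()
  for (k in k_range) {
    conn_sum <- matrix(0, n, n)
    used <- 0L
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(v, k, seed = derive_seed(seed, 1000L * k + r),
                           max_iter = max_iter, tol = tol)
      lab <- apply(fit$h, 2, which.max)
      if (length(unique(lab)) < 2) {
        warning(sprintf("degenerate NMF run (k=%d, run %d) excluded from consensus", k, r),
                call. = FALSE)
        next
      }
      conn_sum <- conn_sum + outer(lab, lab, "==")
      used <- used + 1L
    }
    if (used == 0L) stop("all NMF runs degenerate at k=", k, call. = FALSE)
    consensus <- conn_sum / used
    dimnames(consensus) <- list(samples, samples)
    diss <- as.dist(1 - consensus)
    tree <- hclust(diss, method = "average")
    rho <- suppressWarnings(cor(as.vector(diss), as.vector(cophenetic(tree))))
    if (!is.finite(rho)) rho <- 1  # zero-dissimilarity consensus: perfectly ultrametric
    labels <- cutree(tree, k = k)
    per_k[[as.character(k)]] <- list(
      consensus = consensus, cophenetic = rho,
      labels = stats::setNames(labels, samples), n_runs_used = used
    )
  }
  res <- structure(
    list(k_range = as.integer(k_range), per_k = per_k, k_selected = NA_integer_,
         filtered_genes = rownames(v)),
    class = "subtyping_result"
  )
  if (length(k_range) >= 3) {
    res$k_selected <- select_k(cophenetic_profile(res))
  }
  res
}

#' Cophenetic coefficients of a subtyping result
#'
#' @param result A `subtyping_result`.
#' @return Named numeric vector, names = ranks.
#' @export
cophenetic_profile <- function(result) {
  stopifnot(inherits(result, "subtyping_result"))
  vapply(result$per_k, `[[`, numeric(1), "cophenetic")
}

#' Select the factorization rank before the steepest cophenetic fall
#'
#' Given cophenetic coefficients over consecutive candidate ranks, returns the
#' rank immediately preceding the steepest fall. The fall from `k` to `k + 1`
#' is measured on the scale of the consensus's departure from a perfectly
#' ultrametric (crisp) structure: `fall(k) = (1 - rho(k+1)) / (1 - rho(k))`.
#' At the true rank the consensus is essentially crisp (`rho` within numerical
#' noise of 1) and one rank beyond it the departure grows by an order of
#' magnitude, so the relative fall peaks sharply there; an absolute difference
#' `rho(k) - rho(k+1)` would instead drift toward the top of the candidate
#' range whenever `rho` decays convexly. The selected rank is
#' `argmax_k fall(k)` over all but the last candidate, ties broken toward the
#' smaller rank; `0/0` falls count as 1 (no change). If no coefficient
#' actually decreases a "no fall detected" warning is emitted and the tie rule
#' still applies.
#'
#' @param rho Named numeric vector of cophenetic coefficients; names are the
#'   (>= 3, consecutive) candidate ranks.
#' @return The selected rank as an integer.
#' @export
select_k <- function(rho) {
  if (any(!is.finite(rho))) stop("non-finite cophenetic coefficient", call. = FALSE)
  ks <- as.integer(names(rho))
  stopifnot(length(ks) >= 3, all(diff(ks) == 1L))
  gap <- 1 - rho
  num <- gap[-1]
  den <- gap[-length(gap)]
  fall <- ifelse(den == 0 & num == 0, 1, num / den)
  drops <- rho[-length(rho)] - rho[-1]
  if (max(drops) <= 0) {
    warning("no cophenetic fall detected; returning smallest candidate by tie rule",
            call. = FALSE)
  }
  ks[which.max(fall)]
}

#' Subtype a cohort by NMF consensus clustering
#'
#' The full subtyping stage: filter genes by mean absolute deviation, shift
#' the log-scale matrix to be non-negative, run consensus clustering over the
#' candidate ranks, and select the rank before the steepest cophenetic fall.
#'
#' @param x An [expr_matrix()] (log2-normalized).
#' @param k_range Candidate ranks (>= 3 consecutive values).
#' @param mad_threshold,mad_top_n Passed to [mad_filter()].
#' @param n_runs NMF restarts per rank.
#' @param seed Master seed.
#' @param ... Passed to [consensus_cluster()].
#' @return A `subtyping_result` with `k_selected` set and `filtered_genes`
#'   recording the genes used.
#' @export
nmf_subtype <- function(x, k_range = 2:6, mad_threshold = 1.0, mad_top_n = NULL,
                        n_runs = 30L, seed = 1L, ...) {
  genes <- mad_filter(x, threshold = mad_threshold, top_n = mad_top_n)
  v <- shift_nonneg(x[genes, , drop = FALSE])
  consensus_cluster(v, k_range = k_range, n_runs = n_runs, seed = seed, ...)
}

#' Cluster labels from a subtyping result
#'
#' @param result A `subtyping_result`.
#' @param k Rank whose labels to return; defaults to the selected rank.
#' @return Tibble with `sample_id` and integer `cluster`.
#' @export
subtype_labels <- function(result, k = NULL) {
  stopifnot(inherits(result, "subtyping_result"))
  k <- k %||% result$k_selected
  if (is.na(k)) stop("no rank selected; pass `k`", call. = FALSE)
  lab <- result$per_k[[as.character(k)]]$labels
  tibble::tibble(sample_id = names(lab), cluster = unname(lab))
}

#' @export
print.subtyping_result <- function(x, ...) {
  cat(sprintf("<subtyping_result> ranks %s; selected k = %s; %d genes\n",
              paste(range(x$k_range), collapse = ".."),
              ifelse(is.na(x$k_selected), "not set", x$k_selected),
              length(x$filtered_genes)))
  invisible(x)
}

#' @method tidy subtyping_result
#' @export
tidy.subtyping_result <- function(x, ...) {
  tibble::tibble(
    k = x$k_range,
    cophenetic = unname(cophenetic_profile(x)),
    n_runs_used = vapply(x$per_k, `[[`, integer(1), "n_runs_used"),
    selected = !is.na(x$k_selected) & x$k_range == x$k_selected
  )
}

#' @method glance subtyping_result
#' @export
glance.subtyping_result <- function(x, ...) {
  tibble::tibble(
    k_selected = x$k_selected,
    n_genes = length(x$filtered_genes),
    n_samples = ncol(x$per_k[[1]]$consensus),
    cophenetic_at_selected = if (!is.na(x$k_selected)) {
      x$per_k[[as.character(x$k_selected)]]$cophenetic
    } else {
      NA_real_
    }
  )
}
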