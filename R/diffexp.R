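# Differential expression: empirical-Bayes moderated t-tests, BH correction,
# one-vs-both-others subtype signatures, and the immune-candidate filter.

#' Moderated two-group t-test per gene
#'
#' Per gene, the log2 fold change is `mean(A) - mean(B)` (log-scale input) and
#' the pooled residual variance `s^2` has `d = |A| + |B| - 2` degrees of
#' freedom. A scaled inverse-chi-square prior `(d0, s0^2)` is fitted across
#' genes by moment matching on `log(s^2)`; the posterior variance
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` shrinks each gene's variance
#' toward the prior, and `t = log2fc / (s_tilde * sqrt(1/|A| + 1/|B|))` is
#' referred to a t distribution with `d + d0` degrees of freedom. `d0 = 0`
#' reproduces the ordinary pooled t-test; `d0 = Inf` tests against the common
#' prior variance alone.
#'
#' @param x An [expr_matrix()].
#' @param group_a,group_b Disjoint observation-id vectors, each of size >= 2.
#' @param contrast Label recorded in the output.
#' @param d0,s0_sq Optional prior values; by default both are estimated by
#'   the moment fit. When the fit finds no excess variability beyond sampling,
#'   the moment answer is `d0 = Inf` (full shrinkage).
#' @param fc_cut,q_cut Thresholds defining `direction`: `up` iff
#'   `log2fc > fc_cut` and `q < q_cut`, `down` symmetrically, else `ns`.
#' @return Tibble (`gene`, `contrast`, `log2fc`, `t_stat`, `df`, `p`, `q`,
#'   `direction`) with BH-adjusted `q` within the contrast.
#' @export
moderated_t <- function(x, group_a, group_b, contrast = "A_vs_B",
                        d0 = NULL, s0_sq = NULL, fc_cut = 1, q_cut = 0.05) {
  obs <- obs_ids(x)
  stopifnot(all(group_a %in% obs), all(group_b %in% obs))
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap", call. = FALSE)
  }
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 observations", call. = FALSE)

  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  fc <- ma - mb
  d <- na + nb - 2
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d

  if (is.null(d0) || is.null(s0_sq)) {
    fit <- fit_variance_prior(s2, d)
    if (is.null(d0)) d0 <- fit$d0
    if (is.null(s0_sq)) s0_sq <- fit$s0_sq
  }

  if (is.infinite(d0)) {
    stilde2 <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    stilde2 <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d + d0
  }
  se <- sqrt(stilde2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[se == 0 & fc == 0] <- 1
  q <- bh_adjust(p)
  tibble::tibble(
    gene = gene_ids(x), contrast = contrast, log2fc = unname(fc),
    t_stat = unname(tstat), df = df_total, p = unname(p), q = unname(q),
    direction = dplyr::case_when(
      log2fc > fc_cut & q < q_cut ~ "up",
      log2fc < -fc_cut & q < q_cut ~ "down",
      TRUE ~ "ns"
    )
  )
}

# Moment-matching fit of a scaled inverse-chi-square prior to per-gene
# variances via the distribution of log(s^2) (Smyth's method): with
# e = log(s2) - digamma(d/2) + log(d/2), solve
# trigamma(d0/2) = var(e) - trigamma(d/2).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    warning("too few positive variances for the moment fit; using d0 = 0", call. = FALSE)
    return(list(d0 = 0, s0_sq = stats::median(s2)))
  }
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar)) {
    warning("variance moment fit failed; using d0 = 0", call. = FALSE)
    return(list(d0 = 0, s0_sq = exp(mean(e))))
  }
  if (evar <= 0) {
    # no excess variability across genes beyond sampling: prior df infinite
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(x) = y (monotone decreasing).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`stats::p.adjust` with
#' `method = "BH"`), with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' One-vs-both-others subtype signatures
#'
#' For each subtype, [moderated_t()] is run against each other subtype
#' separately (BH adjustment within each contrast). A gene is "up" in a
#' subtype iff it passes `log2fc > fc_cut` and `q < q_cut` in *both* pairwise
#' contrasts, and symmetrically for "down". Up genes are ranked by descending
#' minimum pairwise log2 fold change, down genes by ascending maximum.
#'
#' @param x An [expr_matrix()].
#' @param labels Tibble (`sample_id`, `subtype`) or named vector mapping
#'   samples to subtypes; every subtype needs >= 2 samples.
#' @param fc_cut,q_cut Signature thresholds.
#' @return An object of class `subtype_signatures`: list with `signatures`
#'   (per subtype: ranked `up` and `down` gene vectors), `table` (tidy long
#'   form) and `contrasts` (all pairwise DEG tables).
#' @export
subtype_signatures <- function(x, labels, fc_cut = 1, q_cut = 0.05) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]), labels[[1]])
  }
  labels <- labels[obs_ids(x)[obs_ids(x) %in% names(labels)]]
  subtypes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("subtype(s) with < 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  contrasts <- list()
  sigs <- list()
  rows <- list()
  for (st in subtypes) {
    others <- setdiff(subtypes, st)
    degs <- lapply(others, function(ot) {
      moderated_t(x, names(labels)[labels == st], names(labels)[labels == ot],
                  contrast = paste0(st, "_vs_", ot), fc_cut = fc_cut, q_cut = q_cut)
    })
    names(degs) <- others
    contrasts <- c(contrasts, degs)
    up_flags <- Reduce(`&`, lapply(degs, function(d) d$direction == "up"))
    down_flags <- Reduce(`&`, lapply(degs, function(d) d$direction == "down"))
    min_fc <- do.call(pmin, lapply(degs, `[[`, "log2fc"))
    max_fc <- do.call(pmax, lapply(degs, `[[`, "log2fc"))
    genes <- degs[[1]]$gene
    up <- genes[up_flags][order(-min_fc[up_flags])]
    down <- genes[down_flags][order(max_fc[down_flags])]
    sigs[[st]] <- list(up = up, down = down)
    if (length(up) > 0) {
      rows[[paste0(st, "_up")]] <- tibble::tibble(
        subtype = st, gene = up, direction = "up",
        rank = seq_along(up), min_pairwise_log2fc = sort(min_fc[up_flags], decreasing = TRUE)
      )
    }
    if (length(down) > 0) {
      rows[[paste0(st, "_down")]] <- tibble::tibble(
        subtype = st, gene = down, direction = "down",
        rank = seq_along(down), min_pairwise_log2fc = sort(max_fc[down_flags])
      )
    }
  }
  structure(
    list(signatures = sigs, table = dplyr::bind_rows(rows),
         contrasts = contrasts, fc_cut = fc_cut, q_cut = q_cut),
    class = "subtype_signatures"
  )
}

#' @export
print.subtype_signatures <- function(x, ...) {
  for (st in names(x$signatures)) {
    cat(sprintf("%s: %d up, %d down\n", st,
                length(x$signatures[[st]]$up), length(x$signatures[[st]]$down)))
  }
  invisible(x)
}

#' @method tidy subtype_signatures
#' @export
tidy.subtype_signatures <- function(x, ...) x$table

#' Immune candidate genes from subtype signatures
#'
#' Candidates are the genes upregulated in the S1-like (hot) or S3-like
#' (immunosuppressed) subtype that are immune genes, minus the genes
#' upregulated in the S2-like (cold) subtype:
#' `((up(S1) | up(S3)) & immune) \ up(S2)`. Signature ranking order is
#' preserved. With `strict = TRUE`, genes differentially expressed in the
#' S2-like subtype in either direction are excluded.
#'
#' @param sigs A `subtype_signatures` object.
#' @param immune_genes Character vector of immune genes.
#' @param s1,s2,s3 Subtype names in `sigs` playing the hot / cold /
#'   immunosuppressed roles.
#' @param strict Also exclude S2-downregulated genes.
#' @return Character vector of candidate genes.
#' @export
immune_candidate_filter <- function(sigs, immune_genes, s1, s2, s3, strict = FALSE) {
  stopifnot(inherits(sigs, "subtype_signatures"))
  missing <- setdiff(c(s1, s2, s3), names(sigs$signatures))
  if (length(missing) > 0) {
    stop("subtype(s) not in signatures: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pool <- unique(c(sigs$signatures[[s1]]$up, sigs$signatures[[s3]]$up))
  excl <- sigs$signatures[[s2]]$up
  if (strict) excl <- c(excl, sigs$signatures[[s2]]$down)
  out <- setdiff(intersect(pool, immune_genes), excl)
  if (length(out) == 0) {
    warning("no immune candidate genes after filtering", call. = FALSE)
  }
  out
}
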