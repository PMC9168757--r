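# Survival stratification: Kaplan-Meier estimation and log-rank testing (via
# the survival package) and an exhaustive expression-cutoff scan that
# maximizes the log-rank statistic within a central percentile window — the
# optimal-cutoff procedure popularized by X-tile, with the minimum-p selection
# bias flagged and an optional permutation-adjusted p.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group; right-censoring is handled by risk-set
#' decrement. With no events the curve is identically 1 (warned).
#'
#' @param data Tibble with `time` (days, > 0), `event` (logical or 0/1) and
#'   optionally `group`.
#' @return Tidy step-function tibble (`group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`).
#' @export
km_estimate <- function(data) {
  check_survival_data(data)
  if (sum(data$event) == 0) {
    warning("no events; survival curve is identically 1", call. = FALSE)
  }
  has_group <- "group" %in% names(data)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = data)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (has_group) {
    sub("^group=", "", as.character(s$strata))
  } else {
    rep("all", length(s$time))
  }
  tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv
  )
}

check_survival_data <- function(data) {
  stopifnot(all(c("time", "event") %in% names(data)))
  if (any(data$time <= 0)) stop("survival times must be positive", call. = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (hypergeometric variance summed over event
#' times) with p from a chi-square distribution with 1 df. Zero variance
#' (e.g. no events) yields chi2 = 0, p = 1 with a warning.
#'
#' @param data Tibble with `time`, `event` and a two-level `group` column.
#' @return Tibble (`chi2`, `p`, `n`, `n_events`).
#' @export
logrank_test <- function(data) {
  check_survival_data(data)
  stopifnot("group" %in% names(data))
  groups <- unique(data$group)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (sum(data$event) == 0) {
    warning("no events; log-rank undefined, returning chi2 = 0, p = 1", call. = FALSE)
    return(tibble::tibble(chi2 = 0, p = 1, n = nrow(data), n_events = 0L))
  }
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group, data = data),
    error = function(e) NULL
  )
  chi2 <- if (is.null(sd_fit) || !is.finite(sd_fit$chisq)) {
    warning("zero log-rank variance; returning chi2 = 0, p = 1", call. = FALSE)
    0
  } else {
    sd_fit$chisq
  }
  tibble::tibble(
    chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
    n = nrow(data), n_events = sum(data$event)
  )
}

#' Optimal expression cutoff by exhaustive log-rank scan
#'
#' Candidate cutoffs are the observed marker values between the `lower_q` and
#' `upper_q` percentiles; each splits the cohort at `marker >= cutoff`
#' (subject to a minimum group fraction) and the cutoff maximizing the
#' log-rank chi-square is returned. The reported `p_raw` is the raw minimum p
#' and carries a selection-bias caveat; `adjust = TRUE` additionally reports a
#' permutation-adjusted p (max-statistic null from permuting the marker).
#'
#' @param marker Named numeric vector (names = sample ids) or a column name in
#'   `data`.
#' @param data Tibble with `sample_id`, `time`, `event` (>= 20 samples).
#' @param lower_q,upper_q Percentile window for candidate cutoffs.
#' @param min_frac Minimum fraction of samples on each side of a split.
#' @param adjust Also compute a permutation-adjusted p.
#' @param n_perm,seed Permutation parameters.
#' @return Tibble (`cutoff`, `chi2`, `p_raw`, `p_adjusted`, `n_candidates`,
#'   `selection_bias_caveat`).
#' @export
optimal_cutoff <- function(marker, data, lower_q = 0.1, upper_q = 0.9,
                           min_frac = 0.1, adjust = FALSE, n_perm = 1000L,
                           seed = 1L) {
  check_survival_data(data)
  stopifnot("sample_id" %in% names(data))
  if (is.character(marker) && length(marker) == 1) {
    marker <- stats::setNames(data[[marker]], data$sample_id)
  }
  marker <- marker[data$sample_id]
  if (nrow(data) < 20) stop("need >= 20 samples for a cutoff scan", call. = FALSE)
  if (length(unique(marker)) == 1) stop("marker is constant", call. = FALSE)
  best <- scan_cutoffs(marker, data$time, data$event, lower_q, upper_q, min_frac)
  p_adj <- NA_real_
  if (adjust) {
    set.seed(derive_seed(seed, 555L))
    null_max <- vapply(seq_len(n_perm), function(b) {
      scan_cutoffs(sample(marker), data$time, data$event,
                   lower_q, upper_q, min_frac)$chi2
    }, numeric(1))
    p_adj <- (1 + sum(null_max >= best$chi2)) / (n_perm + 1)
  }
  tibble::tibble(
    cutoff = best$cutoff, chi2 = best$chi2,
    p_raw = pchisq(best$chi2, df = 1, lower.tail = FALSE),
    p_adjusted = p_adj, n_candidates = best$n_candidates,
    selection_bias_caveat = TRUE
  )
}

scan_cutoffs <- function(marker, time, event, lower_q, upper_q, min_frac) {
  qs <- quantile(marker, c(lower_q, upper_q), type = 7)
  cand <- sort(unique(marker[marker >= qs[1] & marker <= qs[2]]))
  n <- length(marker)
  best_chi2 <- -Inf
  best_cut <- NA_real_
  n_used <- 0L
  for (ct in cand) {
    hi <- marker >= ct
    if (mean(hi) < min_frac || mean(!hi) < min_frac) next
    n_used <- n_used + 1L
    res <- suppressWarnings(logrank_test(tibble::tibble(
      time = time, event = event, group = ifelse(hi, "high", "low")
    )))
    if (res$chi2 > best_chi2) {
      best_chi2 <- res$chi2
      best_cut <- ct
    }
  }
  if (n_used == 0L) {
    stop("no candidate cutoff satisfies the group-size constraint", call. = FALSE)
  }
  list(cutoff = best_cut, chi2 = best_chi2, n_candidates = n_used)
}
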