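# Gene filtering, the NMF factorizer, consensus clustering and rank selection.

test_that("mad_filter implements mean absolute deviation about the mean", {
  x <- toy_matrix(rbind(c(0, 2, 4), c(5, 5, 5), c(1, 1.5, 2)))
  # gene 1: mean 2, mean |dev| = (2 + 0 + 2) / 3 = 4/3 > 1 -> kept
  expect_identical(mad_filter(x, threshold = 1), "g1")
  # constant gene dropped even at threshold 0; non-constant kept
  expect_identical(mad_filter(x, threshold = 0), c("g1", "g3"))
  expect_error(mad_filter(x, threshold = 10), "lower")
  expect_identical(mad_filter(x, top_n = 2), c("g1", "g3"))
})

test_that("nmf_factorize recovers an exactly factorizable matrix", {
  set.seed(1)
  v <- outer(runif(30, 1, 2), runif(12, 1, 2))
  dimnames(v) <- list(sprintf("g%d", 1:30), sprintf("s%d", 1:12))
  fit <- nmf_factorize(v, k = 1, seed = 2)
  expect_lt(fit$rel_error, 1e-3)
  expect_true(all(fit$w >= 0), all(fit$h >= 0))
})

test_that("multiplicative updates never increase the loss", {
  set.seed(0)
  v <- matrix(runif(50 * 20, 0, 10), 50, 20,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:20)))
  fit <- nmf_factorize(v, k = 4, seed = 0)
  expect_true(all(diff(fit$loss) <= 1e-8))
})

test_that("higher rank fits at least as well as rank 1", {
  set.seed(3)
  v <- matrix(runif(40 * 15, 0, 5), 40, 15,
              dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:15)))
  e1 <- nmf_factorize(v, 1, seed = 1)$rel_error
  e14 <- nmf_factorize(v, 14, seed = 1)$rel_error
  expect_lt(e14, e1)
})

test_that("nmf_factorize rejects invalid input", {
  v <- toy_matrix(matrix(c(-1, 2, 3, 4), 2, 2))
  expect_error(nmf_factorize(v, 1), "shift_nonneg")
  v2 <- toy_matrix(matrix(1:4 + 0, 2, 2))
  expect_error(nmf_factorize(v2, 2), "k must satisfy")
})

test_that("consensus on well-separated blocks is crisp", {
  set.seed(1)
  # two planted blocks, noise sd 0.3
  mu <- cbind(matrix(rep(c(3, 0), c(30, 30)), 60, 20),
              matrix(rep(c(0, 3), c(30, 30)), 60, 20))
  v <- pmax(mu + 5 + rnorm(60 * 40, sd = 0.3), 0)
  dimnames(v) <- list(sprintf("g%d", 1:60), sprintf("s%d", 1:40))
  res <- consensus_cluster(v, k_range = 2L, n_runs = 10, seed = 1)
  cm <- res$per_k[["2"]]$consensus
  block <- rep(c(TRUE, FALSE), each = 20)
  same <- outer(block, block, "==")
  off <- upper.tri(cm)
  expect_gte(min(cm[off & same]), 0.95)
  expect_lte(max(cm[off & !same]), 0.05)
  # structural invariants
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 40))
  expect_true(all(cm >= 0 & cm <= 1))
  # determinism
  res2 <- consensus_cluster(v, k_range = 2L, n_runs = 10, seed = 1)
  expect_identical(res$per_k[["2"]]$consensus, res2$per_k[["2"]]$consensus)
})

test_that("a perfectly block-diagonal consensus has cophenetic coefficient 1", {
  set.seed(2)
  mu <- cbind(matrix(rep(c(4, 0), c(25, 25)), 50, 15),
              matrix(rep(c(0, 4), c(25, 25)), 50, 15))
  v <- pmax(mu + 5 + rnorm(50 * 30, sd = 0.2), 0)
  dimnames(v) <- list(sprintf("g%d", 1:50), sprintf("s%d", 1:30))
  res <- consensus_cluster(v, k_range = 2L, n_runs = 8, seed = 3)
  cm <- res$per_k[["2"]]$consensus
  expect_true(all(cm %in% c(0, 1)))
  expect_equal(res$per_k[["2"]]$cophenetic, 1)
})

test_that("fully degenerate runs are an error", {
  v <- toy_matrix(matrix(5, 20, 10) + 1e-9)
  expect_error(
    suppressWarnings(consensus_cluster(v, k_range = 2L, n_runs = 3, seed = 1)),
    "degenerate"
  )
})

test_that("cophenetic profile is invariant to sample order", {
  b <- cached_bulk(1)
  genes <- mad_filter(b$expression)
  v <- shift_nonneg(b$expression[genes, ])
  res <- consensus_cluster(v, k_range = 3L, n_runs = 6, seed = 2)
  perm <- sample(ncol(v))
  res_p <- consensus_cluster(v[, perm], k_range = 3L, n_runs = 6, seed = 2)
  # the seeded initializations are drawn per column, so permuting samples can
  # nudge individual restarts; the coefficient itself must not move materially
  expect_equal(res$per_k[["3"]]$cophenetic, res_p$per_k[["3"]]$cophenetic,
               tolerance = 0.01)
})

test_that("select_k follows the steepest relative cophenetic fall", {
  expect_identical(select_k(c(`2` = 0.99, `3` = 0.98, `4` = 0.80, `5` = 0.78)), 3L)
  expect_warning(k <- select_k(c(`2` = 0.5, `3` = 0.6, `4` = 0.8)), "no cophenetic fall")
  expect_identical(k, 2L)
  expect_warning(k <- select_k(c(`2` = 0.9, `3` = 0.9, `4` = 0.9)), "no cophenetic fall")
  expect_identical(k, 2L)
  expect_error(select_k(c(`2` = 0.9, `3` = NA, `4` = 0.8)), "non-finite")
  expect_error(select_k(c(`2` = 0.9, `3` = 0.8)), "length")
  # a crisp consensus at the true rank followed by fuzz is a sharp fall
  expect_identical(select_k(c(`2` = 0.997, `3` = 0.99995, `4` = 0.9985, `5` = 0.996)), 3L)
})

test_that("subtype_labels and tidiers expose the result", {
  b <- cached_bulk(1)
  res <- nmf_subtype(b$expression, k_range = 2:4, n_runs = 5, seed = 1)
  td <- tidy(res)
  expect_identical(td$k, 2:4)
  expect_true(all(td$cophenetic >= -1 & td$cophenetic <= 1))
  lab <- subtype_labels(res, k = 3)
  expect_identical(nrow(lab), ncol(b$expression))
  expect_identical(sort(unique(lab$cluster)), 1:3)
  gl <- glance(res)
  expect_identical(gl$k_selected, res$k_selected)
})
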