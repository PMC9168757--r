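# Moderated t-tests, BH correction, subtype signatures, immune candidates.

test_that("d0 = 0 reproduces the ordinary pooled t-test gene by gene", {
  set.seed(8)
  x <- toy_matrix(matrix(rnorm(100 * 12, 5), 100, 12))
  a <- sprintf("s%d", 1:6)
  b <- sprintf("s%d", 7:12)
  mod <- moderated_t(x, a, b, d0 = 0, s0_sq = 1)
  classic <- apply(unclass(x), 1, function(v) {
    tt <- stats::t.test(v[1:6], v[7:12], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(mod$t_stat, unname(classic[1, ]), tolerance = 1e-10)
  expect_equal(mod$p, unname(classic[2, ]), tolerance = 1e-10)
})

test_that("d0 = Inf tests against the prior variance alone", {
  set.seed(9)
  x <- toy_matrix(matrix(rnorm(50 * 8, 5), 50, 8))
  a <- sprintf("s%d", 1:4)
  b <- sprintf("s%d", 5:8)
  s0 <- 1.7
  mod <- moderated_t(x, a, b, d0 = Inf, s0_sq = s0)
  fc <- rowMeans(unclass(x)[, a]) - rowMeans(unclass(x)[, b])
  expect_equal(mod$t_stat, unname(fc / sqrt(s0 * (1 / 4 + 1 / 4))), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(10)
  m <- matrix(rnorm(400 * 16, 5), 400, 16,
              dimnames = list(sprintf("g%d", 1:400), sprintf("s%d", 1:16)))
  m[1:40, 1:8] <- m[1:40, 1:8] + 1.5
  x <- expr_matrix(m)
  mine <- moderated_t(x, sprintf("s%d", 1:8), sprintf("s%d", 9:16))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 8))))
  expect_equal(mine$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(mine$t_stat, fit$t[, 2]), 0.9999)
  expect_lt(max(abs(mine$p - fit$p.value[, 2])), 0.01)
})

test_that("null data yields calibrated p-values", {
  set.seed(21)
  m <- matrix(rnorm(2000 * 40, 5), 2000, 40,
              dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:40)))
  d <- moderated_t(expr_matrix(m), sprintf("s%d", 1:20), sprintf("s%d", 21:40))
  expect_gt(mean(d$p < 0.05), 0.03)
  expect_lt(mean(d$p < 0.05), 0.07)
})

test_that("p-values are invariant to a constant expression shift", {
  set.seed(11)
  m <- matrix(rnorm(60 * 10, 5), 60, 10,
              dimnames = list(sprintf("g%d", 1:60), sprintf("s%d", 1:10)))
  a <- sprintf("s%d", 1:5); b <- sprintf("s%d", 6:10)
  p1 <- moderated_t(expr_matrix(m), a, b)$p
  p2 <- moderated_t(expr_matrix(m + 100), a, b)$p
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("zero-variance zero-difference genes get p = 1; overlap errors", {
  m <- rbind(rep(5, 8), matrix(rnorm(40, 3), 5, 8))
  dimnames(m) <- list(sprintf("g%d", 1:6), sprintf("s%d", 1:8))
  x <- expr_matrix(m)
  d <- moderated_t(x, sprintf("s%d", 1:4), sprintf("s%d", 5:8), d0 = 0, s0_sq = 1)
  expect_equal(d$p[1], 1)
  expect_error(moderated_t(x, sprintf("s%d", 1:4), sprintf("s%d", 4:8)), "overlap")
})

test_that("bh_adjust matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  p <- runif(200)
  q <- bh_adjust(p)
  # q is monotone in p: sorting by p sorts q non-decreasingly
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("subtype signatures recover planted programs with high precision", {
  b <- cached_bulk(1)
  sigs <- subtype_signatures(b$expression,
                             tibble::tibble(sample_id = names(b$truth$sample_subtype),
                                            subtype = unname(b$truth$sample_subtype)))
  for (st in c("hot", "cold", "suppressed")) {
    up <- sigs$signatures[[st]]$up
    planted <- b$truth$programs[[st]]
    expect_true(all(planted %in% up))
    expect_gte(mean(up %in% planted), 0.95)
    expect_length(intersect(up, sigs$signatures[[st]]$down), 0)
  }
})

test_that("permuted labels yield almost no signature genes", {
  b <- cached_bulk(1)
  set.seed(1)
  labels <- tibble::tibble(
    sample_id = names(b$truth$sample_subtype),
    subtype = sample(unname(b$truth$sample_subtype))
  )
  sigs <- subtype_signatures(b$expression, labels)
  n_hit <- length(unique(unlist(lapply(sigs$signatures, unlist))))
  expect_lte(n_hit, 0.01 * nrow(b$expression))
})

test_that("a gene must pass both pairwise contrasts to enter a signature", {
  set.seed(13)
  m <- matrix(rnorm(30 * 18, 5, 0.2), 30, 18,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:18)))
  grp <- rep(c("k", "o1", "o2"), each = 6)
  m[1, grp == "k"] <- m[1, grp == "k"] + 3      # up vs both
  m[2, grp == "o2"] <- m[2, grp == "o2"] - 3    # g2: up in k vs o2 only
  sigs <- subtype_signatures(expr_matrix(m),
                             tibble::tibble(sample_id = colnames(m), subtype = grp))
  expect_true("g1" %in% sigs$signatures$k$up)
  expect_false("g2" %in% sigs$signatures$k$up)
  expect_error(subtype_signatures(expr_matrix(m),
                                  tibble::tibble(sample_id = colnames(m)[1:13],
                                                 subtype = grp[1:13])),
               "< 2 samples")
})

test_that("immune candidate filter applies the stated set algebra", {
  sigs <- structure(list(signatures = list(
    S1 = list(up = c("a", "b"), down = character(0)),
    S2 = list(up = "b", down = "d"),
    S3 = list(up = "c", down = character(0))
  )), class = "subtype_signatures")
  expect_identical(
    immune_candidate_filter(sigs, c("a", "b", "c", "d"), "S1", "S2", "S3"),
    c("a", "c")
  )
  expect_warning(
    out <- immune_candidate_filter(sigs, c("x", "y"), "S1", "S2", "S3"),
    "no immune"
  )
  expect_length(out, 0)
  # no-exclusion case and strict mode
  sigs$signatures$S2$up <- character(0)
  expect_identical(immune_candidate_filter(sigs, c("a", "b", "c", "d"), "S1", "S2", "S3"),
                   c("a", "b", "c"))
  expect_identical(
    immune_candidate_filter(sigs, c("a", "b", "c", "d"), "S1", "S2", "S3", strict = TRUE),
    c("a", "b", "c")
  )
  expect_error(immune_candidate_filter(sigs, "a", "S1", "S9", "S3"), "S9")
})
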