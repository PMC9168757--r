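# Count filtering, regulon inference, recovery-curve activity and
# hypergeometric TF selection.

test_that("count filter applies both the sum and detection thresholds", {
  n <- 1000
  m <- matrix(0L, 4, n, dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:n)))
  m[1, 1:6] <- c(4L, 4L, 4L, 4L, 2L, 2L)   # 20 counts in 6 cells -> kept
  m[2, 1] <- 20L                           # 20 counts in 1 cell -> detection fails
  m[3, 1:10] <- c(rep(2L, 5), rep(1L, 5))  # 15 counts: 15 not > 15 -> dropped
  m[4, 1:20] <- 2L                         # 40 counts in 20 cells -> kept
  x <- expr_matrix(m, is_counts = TRUE)
  expect_identical(filter_genes_sc(x), c("g1", "g4"))
  expect_error(filter_genes_sc(toy_matrix(matrix(rnorm(4), 2, 2))), "raw-count")
})

test_that("an exact copy of the TF is always a target; independent genes are not", {
  set.seed(17)
  n <- 2000
  tf <- pmax(rnorm(n, 2), 0)
  m <- rbind(TF = tf, COPY = tf,
             t(replicate(15, rnorm(n, 2))))
  rownames(m) <- c("TF", "COPY", sprintf("noise%d", 1:15))
  colnames(m) <- sprintf("c%d", 1:n)
  x <- expr_matrix(m)
  regs <- infer_regulons(x, "TF", rho_min = 0.3, min_targets = 1)
  expect_identical(regulon_targets(regs, "TF")[1], "COPY")
  expect_equal(regs$regulons$TF$weight[1], 1)
  expect_false(any(grepl("noise", regulon_targets(regs, "TF"))))
  # regulons below min_targets are discarded with a warning
  expect_warning(r2 <- infer_regulons(x, "noise1", rho_min = 0.3, min_targets = 10),
                 "discarded")
  expect_length(r2$regulons, 0)
  expect_error(infer_regulons(x, character(0)), "empty TF list")
  expect_warning(infer_regulons(x, c("TF", "ABSENT"), min_targets = 1), "ABSENT")
})

test_that("independent genes stay out of regulons across seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 5000
    m <- rbind(TF = rnorm(n, 2), G = rnorm(n, 2))
    colnames(m) <- sprintf("c%d", 1:n)
    r <- suppressWarnings(
      infer_regulons(expr_matrix(m), "TF", rho_min = 0.3, min_targets = 1)
    )
    length(r$regulons) > 0
  }, logical(1))
  expect_identical(sum(hits), 0L)
})

test_that("recovery-curve AUC matches enumeration on 4-gene toys", {
  # G = 4, top_frac 0.5 -> k = 2
  x <- toy_matrix(matrix(c(4, 3, 2, 1), 4, 1))
  expect_equal(aucell_scores(x, list(r = "g1"), top_frac = 0.5)$auc, 1)    # rank 1
  expect_equal(aucell_scores(x, list(r = "g2"), top_frac = 0.5)$auc, 0.5)  # rank 2
  expect_equal(aucell_scores(x, list(r = "g4"), top_frac = 0.5)$auc, 0)    # below k
  # two-gene regulon at ranks 1,2: h = (1, 2) -> (1 + 2) / (2 * 2) = 0.75
  expect_equal(aucell_scores(x, list(r = c("g1", "g2")), top_frac = 0.5)$auc, 0.75)
  # ties broken by ascending gene id
  xt <- toy_matrix(matrix(c(5, 5, 5, 5), 4, 1))
  expect_equal(aucell_scores(xt, list(r = "g1"), top_frac = 0.5)$auc, 1)
  expect_equal(aucell_scores(xt, list(r = "g3"), top_frac = 0.5)$auc, 0)
  expect_warning(a <- aucell_scores(x, list(r = "nope"), top_frac = 0.5), "no genes")
  expect_equal(a$auc, 0)
})

test_that("AUC is invariant to monotone transforms and bounded in [0, 1]", {
  set.seed(18)
  m <- matrix(rnorm(100 * 20, 5), 100, 20,
              dimnames = list(sprintf("g%d", 1:100), sprintf("c%d", 1:20)))
  x <- expr_matrix(m)
  set <- list(r = sprintf("g%d", c(3, 10, 44, 70)))
  a1 <- aucell_scores(x, set, top_frac = 0.1)
  a2 <- aucell_scores(expr_matrix(2^m), set, top_frac = 0.1)
  expect_equal(a1$auc, a2$auc)
  expect_true(all(a1$auc >= 0 & a1$auc <= 1))
})

test_that("driver regulon activity is specific to suppressed T cells", {
  for (s in 1:3) {
    sc <- cached_sc(s)
    regs <- suppressWarnings(infer_regulons(sc$expression, sc$truth$tf_genes))
    act <- aucell_scores(sc$expression, regs)
    drv <- act[act$regulon == sc$truth$driver_tf, ]
    drv$type <- sc$truth$cell_type[drv$cell_id]
    means <- tapply(drv$auc, drv$type, mean)
    expect_identical(names(which.max(means)), "SuppressedT")
    expect_true(all(means["SuppressedT"] > means[names(means) != "SuppressedT"]))
  }
})

test_that("hypergeometric p equals the closed form and brute-force enumeration", {
  universe <- sprintf("u%d", 1:10)
  regs <- list(TF = universe[1:5])         # K = 5
  hubs <- c(universe[1:3], universe[6])    # n = 4, overlap x = 3
  out <- hypergeom_tf_selection(hubs, regs, universe, q_max = 0.05)
  expect_equal(out$p, 55 / 210, tolerance = 1e-12)
  expect_equal(out$p, hypergeom_bruteforce(10, 5, 4, 3), tolerance = 1e-12)
  # x = 0 -> p = 1
  out0 <- hypergeom_tf_selection(universe[6:9], list(TF = universe[1:5]), universe)
  expect_equal(out0$p, 1)
  expect_error(hypergeom_tf_selection("zzz", regs, universe), "outside")
  expect_error(hypergeom_tf_selection(hubs, regs, character(0)), "empty universe")
})

test_that("hypergeometric tail matches enumeration across small configurations", {
  for (N in c(8, 10, 12)) {
    universe <- sprintf("u%d", seq_len(N))
    for (K in c(3, 5)) {
      for (n in c(3, 6)) {
        for (x in max(0, n - (N - K)):min(K, n)) {
          hubs <- c(universe[seq_len(x)],
                    if (n - x > 0) universe[K + seq_len(n - x)] else character(0))
          out <- hypergeom_tf_selection(hubs, list(TF = universe[seq_len(K)]), universe)
          expect_equal(out$p, hypergeom_bruteforce(N, K, n, x), tolerance = 1e-12)
        }
      }
    }
  }
})
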