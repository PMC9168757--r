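# Pseudocells, soft-threshold selection, TOM modules and module-trait
# statistics.

test_that("pseudocell partition follows the size and remainder rules", {
  # 10 identical cells -> one pseudocell equal to any cell
  x <- toy_matrix(matrix(rep(c(1, 2, 3), 10), 3, 10), obs = sprintf("c%d", 1:10))
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:10), cell_type = "T")
  pc <- make_pseudocells(x, cells, size = 10, seed = 1)
  expect_identical(ncol(pc$expression), 1L)
  expect_equal(unname(unclass(pc$expression)[, 1]), c(1, 2, 3))

  # 25 cells, size 10 -> remainder of 5 merged into the last group: (10, 15)
  x2 <- toy_matrix(matrix(rnorm(3 * 25), 3, 25), obs = sprintf("c%d", 1:25))
  cells2 <- tibble::tibble(cell_id = sprintf("c%d", 1:25), cell_type = "T")
  pc2 <- make_pseudocells(x2, cells2, size = 10, seed = 2)
  expect_identical(ncol(pc2$expression), 2L)
  # 26 cells -> remainder of 6 > size/2 stays its own pseudocell: (10, 10, 6)
  x3 <- toy_matrix(matrix(rnorm(3 * 26), 3, 26), obs = sprintf("c%d", 1:26))
  cells3 <- tibble::tibble(cell_id = sprintf("c%d", 1:26), cell_type = "T")
  pc3 <- make_pseudocells(x3, cells3, size = 10, seed = 2)
  expect_identical(ncol(pc3$expression), 3L)

  # determinism
  pc2b <- make_pseudocells(x2, cells2, size = 10, seed = 2)
  expect_identical(unclass(pc2$expression), unclass(pc2b$expression))

  # a type below size becomes one pseudocell with a warning
  cells4 <- cells2
  cells4$cell_type[1:4] <- "rare"
  expect_warning(pc4 <- make_pseudocells(x2, cells4, size = 10, seed = 1), "rare")
  expect_true("rare_1" %in% pc4$traits$pseudocell_id)
})

test_that("tom_matrix matches the hand-computed complete graph and is bounded", {
  a <- matrix(1, 3, 3)
  tom <- tom_matrix(a)
  expect_equal(tom, matrix(1, 3, 3))  # (1 + 1) / (2 + 1 - 1) = 1
  set.seed(6)
  m <- matrix(rnorm(200), 20, 10)
  adj <- abs(cor(t(m)))^3
  tom2 <- tom_matrix(adj)
  expect_true(isSymmetric(tom2))
  expect_true(all(tom2 >= 0 & tom2 <= 1 + 1e-12))
  expect_equal(unname(diag(tom2)), rep(1, 20))
})

test_that("adjacency weakly decreases with the soft power", {
  set.seed(7)
  m <- matrix(rnorm(30 * 12), 30, 12)
  cc <- abs(cor(t(m)))
  expect_true(all(cc^3 <= cc^1 + 1e-12))
})

test_that("soft threshold selection returns a usable power on planted data", {
  sc <- cached_sc(1)
  pc <- make_pseudocells(sc$expression, sc$cells, size = 10, seed = 1)
  st <- suppressWarnings(pick_soft_threshold(pc$expression))
  expect_true(st$beta %in% 1:20)
  expect_lte(st$beta, 12)
  expect_identical(nrow(st$fit), 20L)
  expect_true(all(st$fit$r2 >= 0 & st$fit$r2 <= 1))
  # mean connectivity decreases with the power
  expect_true(all(diff(st$fit$mean_connectivity) < 0))
})

test_that("two planted orthogonal programs are recovered as two modules", {
  set.seed(14)
  n_pc <- 60
  # two independent latent programs (uncorrelated, not complementary: an
  # unsigned network would merge perfectly anti-correlated programs)
  z1 <- rnorm(n_pc)
  z2 <- rnorm(n_pc)
  m <- rbind(
    t(replicate(25, 2 * z1 + rnorm(n_pc, sd = 0.5))),
    t(replicate(25, 2 * z2 + rnorm(n_pc, sd = 0.5))),
    matrix(rnorm(10 * n_pc, 1), 10, n_pc)
  )
  x <- toy_matrix(m, obs = sprintf("p%d", seq_len(n_pc)))
  mods <- detect_modules(x, beta = 6)
  expect_identical(nrow(mods$eigengenes), 2L)
  for (prog_genes in list(sprintf("g%d", 1:25), sprintf("g%d", 26:50))) {
    assigned <- mods$modules$module[mods$modules$gene %in% prog_genes]
    main <- as.integer(names(which.max(table(assigned))))
    expect_gt(main, 0)
    inferred <- mods$modules$gene[mods$modules$module == main]
    f1 <- truth_scorecard(inferred_genes = inferred, truth_genes = prog_genes)
    expect_gte(f1$value[f1$metric == "f1"], 0.9)
  }
  # gene-order invariance up to relabeling
  perm <- sample(nrow(m))
  mods_p <- detect_modules(x[perm, ], beta = 6)
  joined <- dplyr::inner_join(mods$modules, mods_p$modules, by = "gene")
  expect_equal(mclust::adjustedRandIndex(joined$module.x, joined$module.y), 1)
})

test_that("a one-gene module's eigengene is the standardized gene, sign +", {
  set.seed(15)
  m <- rbind(
    t(replicate(21, rep(c(2, 0), 15) + rnorm(30, sd = 0.1))),
    lone = sin(1:30)
  )
  x <- toy_matrix(m, obs = sprintf("p%d", 1:30))
  mods <- detect_modules(x, beta = 3, min_module_size = 1)
  lone_mod <- mods$modules$module[mods$modules$gene == "g22"]
  eg <- mods$eigengenes[paste0("M", lone_mod), ]
  expect_equal(stats::sd(eg), 1)
  expect_equal(unname(cor(eg, m["lone", ])), 1, tolerance = 1e-9)
})

test_that("module-trait statistics, MM/GS and hub thresholds behave", {
  sc <- cached_sc(1)
  pc <- make_pseudocells(sc$expression, sc$cells, size = 10, seed = 1)
  mods <- detect_modules(pc$expression, 6)
  mods <- module_trait_stats(mods, pc$traits, pc$expression)
  # a module aligned with a type: r near 1, p tiny
  best <- mods$module_trait[which.max(mods$module_trait$r), ]
  expect_gt(best$r, 0.9)
  expect_lt(best$p, 1e-6)
  # every hub satisfies both thresholds for its module's best trait
  for (mname in names(mods$hubs)) {
    h <- mods$hubs[[mname]]
    if (length(h$genes) == 0) next
    m_id <- as.integer(sub("M", "", mname))
    mm <- mods$mm$mm[match(h$genes, mods$mm$gene)]
    gs <- mods$gs$gs[mods$gs$trait == h$trait][match(h$genes, mods$gs$gene[mods$gs$trait == h$trait])]
    expect_true(all(mm > 0.7))
    expect_true(all(gs > 0.6))
    expect_true(all(mods$modules$module[match(h$genes, mods$modules$gene)] == m_id))
  }
  # eigengene first-PC property: explains at least as much module variance as
  # any single member gene
  m1_genes <- mods$modules$gene[mods$modules$module == 1]
  z <- t(scale(t(unclass(pc$expression[m1_genes, ]))))
  eg <- mods$eigengenes[1, ]
  ev_eigen <- mean(cor(t(z), eg)^2)
  ev_best_gene <- max(vapply(seq_len(nrow(z)), function(i) {
    mean(cor(t(z), z[i, ])^2)
  }, numeric(1)))
  expect_gte(ev_eigen + 1e-8, ev_best_gene)
})

test_that("a constant trait is recorded as r = 0 with a warning", {
  set.seed(16)
  m <- rbind(t(replicate(25, rep(c(2, 0), 20) + rnorm(40, sd = 0.3))),
             matrix(rnorm(10 * 40), 10, 40))
  x <- toy_matrix(m, obs = sprintf("p%d", 1:40))
  mods <- detect_modules(x, 3)
  traits <- tibble::tibble(pseudocell_id = sprintf("p%d", 1:40), cell_type = "only")
  expect_warning(out <- module_trait_stats(mods, traits, x), "constant trait")
  expect_equal(out$module_trait$r, rep(0, nrow(out$module_trait)))
})
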