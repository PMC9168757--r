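# Pseudo-bulking, reference labeling, the FPR/TPR panel sweep and cohort
# classification.

test_that("pseudo_bulk averages cells per sample and ignores cell order", {
  x <- toy_matrix(matrix(c(2, 1, 4, 3, 10, 8), 2, 3), obs = c("c1", "c2", "c3"))
  cells <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                          sample_id = c("sa", "sa", "sb"))
  pb <- pseudo_bulk(x, cells)
  expect_equal(unclass(pb)[, "sa"], c(g1 = 3, g2 = 2))
  expect_equal(unclass(pb)[, "sb"], c(g1 = 10, g2 = 8))  # singleton = the cell
  pb2 <- pseudo_bulk(x, cells[c(3, 1, 2), ])
  expect_equal(unclass(pb2)[, colnames(pb)], unclass(pb), ignore_attr = TRUE)
  cells$sample_id[3] <- "gone"
  cells$cell_id[3] <- "missing_cell"
  expect_warning(pb3 <- pseudo_bulk(x, cells), "gone")
  expect_identical(obs_ids(pb3), "sa")
})

test_that("reference labels follow the quartile rule with max-z tie-break", {
  mk <- function(liver, supp, act) {
    tibble::tibble(
      obs_id = rep(sprintf("s%d", seq_along(liver)), 3),
      score_name = rep(c("liver", "immunosuppressed", "activatedT"),
                       each = length(liver)),
      value = c(liver, supp, act)
    )
  }
  # quartile positives (top 2 of 8 per family): liver {s7, s8},
  # immunosuppressed {s1, s2}, activatedT {s3, s7}; s7 is doubly positive and
  # resolves by max z (liver z 1.29 > activatedT z 1.15)
  scores <- mk(liver = c(0, 0, 0, 0, 1, 2, 30, 40),
               supp = c(30, 40, 0, 0, 1, 2, 0, 0),
               act = c(0, 0, 40, 20, 1, 2, 30, 0))
  ref <- build_reference_labels(scores)
  pick <- function(s) ref[ref$sample_id == s, ]
  expect_identical(pick("s8")$class, "cold")
  expect_identical(pick("s8")$basis, "quartile")
  expect_identical(pick("s1")$class, "suppressed")
  expect_identical(pick("s3")$class, "hot")
  expect_identical(pick("s7")$class, "cold")
  expect_identical(pick("s7")$basis, "max_z")
  expect_identical(pick("s7")$n_positive, 2L)
  expect_error(build_reference_labels(scores[scores$obs_id %in% c("s1", "s2"), ]),
               ">= 4")
})

test_that("reference labels recover the planted sample groups", {
  sc <- cached_sc(1)
  ref <- sc_reference(sc)$labels
  agreement <- mean(ref$class == sc$truth$sample_group[ref$sample_id])
  expect_gte(agreement, 0.9)
})

test_that("the sweep finds a perfect panel dominated by planted markers", {
  sc <- cached_sc(1)
  ref <- sc_reference(sc)
  sigs <- subtype_signatures(ref$pseudo_bulk,
                             ref$labels[, c("sample_id", "class")])
  up <- lapply(sigs$signatures, `[[`, "up")
  clf <- panel_sweep(up, ref$pseudo_bulk, ref$labels)
  expect_true(clf$perfect)
  at <- clf$sweep[clf$sweep$n == clf$selected_n, ]
  expect_equal(at$fpr, rep(0, 3))
  expect_equal(at$tpr, rep(1, 3))
  planted <- unlist(sc$truth$markers)
  expect_gte(mean(clf$panel %in% planted), 0.8)
  # recomputation audit: rates at the selected size reproduce exactly
  re <- suppressWarnings(panel_sweep(up, ref$pseudo_bulk, ref$labels,
                                     n_min = clf$selected_n, n_max = clf$selected_n))
  expect_equal(re$sweep[, c("class", "fpr", "tpr")], at[, c("class", "fpr", "tpr")])
  # JSON persistence round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_classifier(clf, path)
  clf2 <- read_panel_classifier(path)
  expect_identical(clf2$panel, clf$panel)
  expect_equal(clf2$centroids, clf$centroids)
  expect_equal(clf2$sweep$fpr, clf$sweep$fpr)
})

test_that("shuffled reference labels cannot be perfectly classified", {
  sc <- cached_sc(1)
  ref <- sc_reference(sc)
  sigs <- subtype_signatures(ref$pseudo_bulk, ref$labels[, c("sample_id", "class")])
  up <- lapply(sigs$signatures, `[[`, "up")
  set.seed(1)
  shuffled <- ref$labels
  # a fixed derangement of the class column
  shuffled$class <- shuffled$class[c(6, 8, 1, 9, 2, 10, 3, 4, 5, 7)]
  expect_warning(clf <- panel_sweep(up, ref$pseudo_bulk, shuffled), "no panel size")
  expect_false(clf$perfect)
})

test_that("classify_cohort is self-consistent and transfers to held-out cohorts", {
  sc <- cached_sc(1)
  ref <- sc_reference(sc)
  sigs <- subtype_signatures(ref$pseudo_bulk, ref$labels[, c("sample_id", "class")])
  clf <- panel_sweep(lapply(sigs$signatures, `[[`, "up"), ref$pseudo_bulk, ref$labels)
  self <- classify_cohort(clf, ref$pseudo_bulk, n_runs = 10, seed = 3)
  expect_identical(
    self$class[match(ref$labels$sample_id, self$sample_id)],
    ref$labels$class
  )
  bulk <- cached_bulk(99)
  pred <- classify_cohort(clf, bulk$expression, n_runs = 10, seed = 3)
  ari <- mclust::adjustedRandIndex(pred$class,
                                   bulk$truth$sample_subtype[pred$sample_id])
  expect_gte(ari, 0.8)
  # sample order invariance
  pred2 <- classify_cohort(clf, bulk$expression[, rev(obs_ids(bulk$expression))],
                           n_runs = 10, seed = 3)
  expect_identical(pred2$class[match(pred$sample_id, pred2$sample_id)], pred$class)
  # coverage contract
  tiny <- bulk$expression[head(clf$panel, floor(length(clf$panel) * 0.4)), ]
  expect_error(classify_cohort(clf, tiny), "50%")
})
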