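test_that("stage and period maps follow the clinical cutoffs", {
  w <- c(0, 1, 6, 9, 10, 13, 14, 27, 28, 40)
  expect_identical(stageFromWeeks(w),
                   c("non-pregnant", "first", "first", "first", "first",
                     "first", "second", "second", "third", "third"))
  expect_identical(stageFromWeeks(w, substage_early = TRUE)[3:6],
                   c("first-early", "first-early", "first-late", "first-late"))
  expect_identical(periodFromWeeks(c(0, 13, 14, 27, 28)),
                   c(NA, "early", "middle", "middle", "late"))
})

test_that("detected-gene bounds keep exactly the boundary cells", {
  ## four cells detecting 799 / 800 / 6000 / 6001 genes
  n_det <- c(799, 800, 6000, 6001)
  m <- Matrix::sparseMatrix(
    i = unlist(lapply(n_det, seq_len)),
    j = rep(seq_along(n_det), n_det),
    x = 1, dims = c(6001, 4),
    dimnames = list(sprintf("G%04d", 1:6001), NULL))
  ds <- toy_cohort(as.matrix(m), gene_names = rownames(m))
  out <- filterCells(ds, qcThresholds())
  expect_identical(sort(detectedGenes(out)), c(800L, 6000L))
  rep <- qcReport(out)
  expect_equal(rep$removed_low_genes, 1)
  expect_equal(rep$removed_high_genes, 1)
})

test_that("the mitochondrial cutoff is inclusive at 5.0%", {
  ## 10 cells with integer counts and total 1000 each, so mito% is exact:
  ## three cells sit at 4.9 / 5.0 / 5.1 percent
  mito_counts <- c(rep(20L, 7), 49L, 50L, 51L)
  mat <- matrix(0L, 1001, 10,
                dimnames = list(c(sprintf("G%04d", 1:1000), "MT-1"), NULL))
  for (j in 1:10) {
    mat[seq_len(1000L - mito_counts[j]), j] <- 1L
    mat["MT-1", j] <- mito_counts[j]
  }
  ds <- toy_cohort(mat, gene_names = rownames(mat))
  expect_equal(mitoPercent(ds)[8:10], c(4.9, 5.0, 5.1))
  out <- filterCells(ds, qcThresholds())
  expect_equal(ncol(out), 9)
  expect_equal(qcReport(out)$removed_high_mito, 1)
  expect_false(any(mitoPercent(out) > 5))
  expect_true(any(mitoPercent(out) == 5.0))
})

test_that("an all-zero dataset retains no cells and filtering is idempotent", {
  ds <- toy_cohort(matrix(0, 5, 4))
  expect_equal(ncol(filterCells(ds, qcThresholds())), 0)

  spec <- cohortSpec(n_subjects = 6, cell_types = c(T = 30), n_genes = 80,
                     n_age_genes = 0, seed = 4)
  co <- generateCohort(spec)$dataset
  thr <- qcThresholds(min_genes = 10, max_genes = 70, max_mito_pct = 6,
                      min_cells_per_type = 5)
  once <- filterCells(co, thr)
  twice <- filterCells(once, thr)
  expect_equal(ncol(twice), ncol(once))
  expect_identical(colnames(twice), colnames(once))
})

test_that("log-normalization matches the closed form and its invariances", {
  ds <- toy_cohort(matrix(c(1, 1, 2), nrow = 3))
  ln <- logNormalize(ds, scale_factor = 4)
  expect_equal(as.numeric(assay(ln, "lognorm")),
               log1p(c(1, 1, 2)), tolerance = 1e-12)
  expect_identical(layerTag(ln), "lognorm")

  ## zero-total cell becomes all-zero, with a warning
  ds0 <- toy_cohort(cbind(c(1, 2, 0), c(0, 0, 0)))
  expect_warning(ln0 <- logNormalize(ds0), "zero total")
  expect_equal(as.numeric(assay(ln0, "lognorm")[, 2]), c(0, 0, 0))

  ## doubling a cell's counts leaves its normalized profile unchanged
  ds2 <- toy_cohort(cbind(c(1, 2, 3), c(2, 4, 6)))
  ln2 <- logNormalize(ds2)
  expect_equal(as.numeric(assay(ln2, "lognorm")[, 1]),
               as.numeric(assay(ln2, "lognorm")[, 2]), tolerance = 1e-12)
})

test_that("cell-type subsetting applies the >= 1000 boundary and partitions cells", {
  sizes <- c(A = 999, B = 1000, C = 5000)
  mat <- matrix(1, 2, sum(sizes))
  ds <- toy_cohort(mat, cell_type = rep(names(sizes), sizes))
  subsets <- subsetCellTypes(ds, qcThresholds())
  expect_setequal(names(subsets), c("B", "C"))
  expect_identical(attr(subsets, "excluded"), "A")
  expect_equal(sum(vapply(subsets, ncol, integer(1))), 6000L)
  expect_equal(ncol(subsets$B), 1000L)

  empty <- subsetCellTypes(ds[, 0], qcThresholds())
  expect_length(empty, 0)

  one <- subsetCellTypes(ds[, cellType(ds) == "C"], qcThresholds())
  expect_length(one, 1)
  expect_identical(colnames(one$C), colnames(ds)[cellType(ds) == "C"])
})

test_that("imputation hook: identity cases and contract error", {
  set.seed(1)
  ds <- logNormalize(toy_cohort(matrix(rpois(300, 4), 15, 20)))
  expect_identical(imputeExpression(ds, "none"), ds)
  k1 <- imputeExpression(ds, "knn_smooth", k = 1, n_pcs = 5)
  expect_equal(as.matrix(assay(k1, "imputed")),
               as.matrix(assay(ds, "lognorm")), tolerance = 1e-10)
  expect_identical(layerTag(k1), "imputed")
  expect_error(imputeExpression(ds, "knn_smooth", k = 20), "smaller")

  ## two identical cells smoothing each other stay unchanged
  m <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 1), c(9, 1, 0, 4), c(9, 1, 0, 4))
  dsi <- logNormalize(toy_cohort(m * 10))
  sm <- imputeExpression(dsi, "knn_smooth", k = 2, n_pcs = 2)
  expect_equal(as.matrix(assay(sm, "imputed")),
               as.matrix(assay(dsi, "lognorm")), tolerance = 1e-10)
})

test_that("gene scaling: unit variance, zero-variance rule, stored-transform round trip", {
  x <- matrix(c(1, 2, 3, 5, 5, 5, 2, 4, 8), nrow = 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  pc <- make_pc(x, ga_days = c(50, 100, 150), layer = "lognorm")
  sc <- scaleGenes(pc)
  sm <- pcExprs(sc$data)
  expect_equal(colMeans(sm), c(g1 = 0, g2 = 0, g3 = 0), tolerance = 1e-12)
  expect_equal(apply(sm, 2, var), c(g1 = 1, g2 = 0, g3 = 1), tolerance = 1e-12)
  expect_equal(sm[, "g2"], rep(0, 3), ignore_attr = TRUE)
  expect_equal(sc$scaler$scale[["g2"]], 1)

  ## stored params reproduce the scaled training data and invert within 1e-10
  again <- applyScaler(x, sc$scaler)
  expect_equal(again, sm, tolerance = 1e-12)
  back <- applyScaler(sm, sc$scaler, inverse = TRUE)
  expect_equal(back, x, tolerance = 1e-10)
})

test_that("scaling a CohortExperiment stores a reusable scaler", {
  set.seed(2)
  ds <- logNormalize(toy_cohort(matrix(rpois(200, 5), 10, 20)))
  sc <- scaleGenes(ds)
  m <- as.matrix(assay(sc$data, "scaled"))
  expect_equal(unname(rowMeans(m)), rep(0, 10), tolerance = 1e-12)
  expect_identical(layerTag(sc$data), "scaled")
  expect_named(sc$scaler, c("center", "scale", "genes"))
})
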