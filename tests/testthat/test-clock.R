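test_that("pseudo-cell counts follow floor(n / group_size) and medians are exact", {
  set.seed(20)
  sizes <- c(S1 = 23, S2 = 10, S3 = 9)
  m <- matrix(rexp(12 * sum(sizes), 1), nrow = 12)
  ds <- toy_lognorm(m, subject = rep(names(sizes), sizes),
                    ga_days = rep(c(70, 140, 210), sizes))
  pc <- makePseudoCells(ds, group_size = 10, seed = 6)
  counts <- table(pcMeta(pc)$subject_id)
  expect_equal(as.integer(counts[c("S1", "S2")]), c(2L, 1L))
  expect_false("S3" %in% names(counts))

  ## brute force: per-gene sorted-median over each recorded group
  lg <- as.matrix(assay(ds, "lognorm"))
  for (i in seq_len(nrow(pcExprs(pc)))) {
    cells <- pcMeta(pc)$cells[[i]]
    expected <- apply(lg[, cells, drop = FALSE], 1, function(v) {
      s <- sort(v); (s[5] + s[6]) / 2
    })
    expect_equal(unname(pcExprs(pc)[i, ]), unname(expected), tolerance = 1e-12)
  }
})

test_that("even-sized group medians use the midpoint convention", {
  m <- matrix(0:9, nrow = 1, dimnames = list("G001", NULL))
  ds <- toy_lognorm(m)
  pc <- makePseudoCells(ds, group_size = 10, seed = 1)
  expect_equal(as.numeric(pcExprs(pc)), 4.5)

  ## identical cells collapse to themselves
  ds2 <- toy_lognorm(matrix(3.3, 5, 12))
  pc2 <- makePseudoCells(ds2, group_size = 4, seed = 1)
  expect_equal(nrow(pcExprs(pc2)), 3)
  expect_true(all(pcExprs(pc2) == 3.3))
})

test_that("pseudo-cell construction rejects bad input", {
  ds <- toy_lognorm(matrix(1, 3, 8))
  expect_error(makePseudoCells(ds, group_size = 0), "group_size")
  ds2 <- toy_lognorm(matrix(1, 3, 8), cell_type = rep(c("A", "B"), 4))
  expect_error(makePseudoCells(ds2), "single cell type")
})

test_that("subject split is stratified, disjoint and deterministic", {
  ## 10 subjects per period stratum -> 7/3 within each
  ages <- c(seq(50, 90, length.out = 10),      # early
            seq(100, 180, length.out = 10),    # middle
            seq(200, 270, length.out = 10))    # late
  ds <- toy_lognorm(matrix(1, 2, 30), subject = sprintf("S%02d", 1:30),
                    ga_days = round(ages))
  plan <- splitSubjects(ds, ratio = 0.7, seed = 3)
  expect_length(plan@trainSubjects, 21)
  expect_length(plan@testSubjects, 9)
  for (per in c("early", "middle", "late")) {
    st <- plan@strata[plan@strata$period == per, ]
    expect_equal(sum(st$side == "train"), 7)
  }
  expect_length(intersect(plan@trainSubjects, plan@testSubjects), 0)

  plan2 <- splitSubjects(ds, ratio = 0.7, seed = 3)
  expect_identical(plan@trainSubjects, plan2@trainSubjects)
  expect_identical(plan@testSubjects, plan2@testSubjects)

  ## no leakage across many seeds; union always covers all subjects
  for (s in 1:200) {
    pl <- splitSubjects(ds, seed = s)
    expect_length(intersect(pl@trainSubjects, pl@testSubjects), 0)
    expect_setequal(c(pl@trainSubjects, pl@testSubjects), sprintf("S%02d", 1:30))
  }
})

test_that("single-subject strata go to training with a warning; controls are excluded", {
  ds <- toy_lognorm(matrix(1, 2, 4), subject = c("A", "B", "C", "NP"),
                    ga_days = c(50, 60, 150, 0))
  expect_warning(plan <- splitSubjects(ds, seed = 1), "single subject")
  expect_true("C" %in% plan@trainSubjects)
  expect_false("NP" %in% c(plan@trainSubjects, plan@testSubjects))
})

test_that("LASSO recovers a planted predictor and orders by coefficient size", {
  set.seed(30)
  n <- 500; p <- 51
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("G%03d", 1:p)))
  y <- round(150 + 5 * x[, "G001"] + rnorm(n, 0, 0.1))
  pc <- make_pc(scale(x), y)
  sel <- selectGenesLasso(pc, penalty = 0.1)
  expect_true("G001" %in% sel)
  expect_identical(sel[1], "G001")
  expect_false(attr(sel, "fallback"))
})

test_that("full shrinkage engages the correlation fallback", {
  set.seed(31)
  x <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(NULL, sprintf("G%03d", 1:20)))
  y <- round(100 + 3 * x[, 2] + rnorm(100, 0, 0.5))
  pc <- make_pc(x, y)
  expect_warning(sel <- selectGenesLasso(pc, penalty = 1e6), "falling back")
  expect_true(attr(sel, "fallback"))
  expect_length(sel, 20)
  expect_identical(sel[1], "G002")
  expect_error(selectGenesLasso(make_pc(x[1, , drop = FALSE], 5), 0.1),
               "at least 2")
})

test_that("a duplicated gene column yields one representative after name dedup", {
  set.seed(32)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, c("A", "B", "C", "D", "B")))
  y <- round(100 + 4 * x[, 2] + rnorm(200, 0, 0.2))
  pc <- make_pc(x, y)
  sel <- selectGenesLasso(pc, penalty = 0.05)
  expect_lte(sum(sel == "B"), 1)
})

test_that("forest tuning: constant target, near-interpolation, determinism", {
  x <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("g", 1:4)))
  pc <- make_pc(x, rep(100L, 120))
  m <- tuneAndTrain(pc, paste0("g", 1:4), n_candidates = 2, cv_folds = 2,
                    seed = 4)
  pr <- predict(m@forest, data = x, num.threads = 1)$predictions
  expect_equal(pr, rep(100, 120), tolerance = 1e-9)
  expect_lt(min(m@cvSummary$cv_rmse), 1e-9)

  set.seed(33)
  x2 <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y2 <- round(100 + 60 * tanh(x2[, 1]))
  pc2 <- make_pc(x2, y2)
  m2 <- tuneAndTrain(pc2, paste0("g", 1:3), n_candidates = 5, cv_folds = 3,
                     seed = 5)
  pr2 <- predict(m2@forest, data = x2, num.threads = 1)$predictions
  expect_gte(cor(pr2, y2), 0.99)

  m2b <- tuneAndTrain(pc2, paste0("g", 1:3), n_candidates = 5, cv_folds = 3,
                      seed = 5)
  expect_identical(m2@hyperParams, m2b@hyperParams)
  expect_identical(m2@cvSummary, m2b@cvSummary)
  expect_error(tuneAndTrain(pc2, paste0("g", 1:3), n_candidates = 0), "n_candidates")
})

test_that("subject-level prediction averages pseudo-cells and scores correctly", {
  m <- fit_toy_clock(n = 150, p = 10, informative = 2, seed = 6)
  set.seed(34)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, sprintf("G%03d", 1:10)))
  subj <- rep(sprintf("T%02d", 1:20), each = 3)
  ages <- rep(round(seq(50, 270, length.out = 20)), each = 3)
  pc <- make_pc(x, ages, subject = subj)
  ev <- predictSubjects(m, pc)
  ## per-subject prediction equals the mean over that subject's pseudo-cells
  pr <- predict(m@forest, data = x, num.threads = 1)$predictions
  manual <- tapply(pr, subj, mean)
  expect_equal(ev@subjects$ga_pred_days,
               as.numeric(manual[ev@subjects$subject_id]), tolerance = 1e-12)
  expect_equal(ev@rmse,
               sqrt(mean((ev@subjects$ga_pred_days - ev@subjects$ga_true_days)^2)),
               tolerance = 1e-12)

  ## prediction is invariant to pseudo-cell ordering
  ord <- sample(60)
  ev2 <- predictSubjects(m, make_pc(x[ord, ], ages[ord], subject = subj[ord]))
  expect_equal(ev2@subjects, ev@subjects, tolerance = 1e-12)

  ## per-period metrics cover the three pregnancy periods
  expect_identical(ev@perPeriod$period, c("early", "middle", "late"))
  expect_equal(sum(ev@perPeriod$n_subjects), nrow(ev@subjects))
})

test_that("evaluation metrics handle perfect, constant and noisy predictions", {
  met <- gestclock:::.subject_metrics
  truth <- seq(50, 270, length.out = 40)
  perfect <- met(truth, truth)
  expect_equal(perfect$R, 1)
  expect_equal(perfect$rmse, 0)

  const <- met(truth, rep(150, 40))
  expect_true(is.na(const$R))
  expect_equal(const$rmse, sqrt(mean((truth - 150)^2)))

  expect_true(is.na(met(truth[1:2], truth[1:2] + 1)$R))

  ## with 40 subjects and sd-10 noise, RMSE^2 * 40/100 ~ chi-square(40):
  ## the exact coverage of the (8, 12) band is ~0.90
  coverage_exact <- pchisq(40 * 1.44, 40) - pchisq(40 * 0.64, 40)
  set.seed(35)
  rmses <- replicate(400, met(truth, truth + rnorm(40, 0, 10))$rmse)
  expect_lt(abs(mean(rmses > 8 & rmses < 12) - coverage_exact), 0.05)
})

test_that("the per-type pipeline retains signal types and rejects noise types", {
  spec <- cohortSpec(n_subjects = 40, cell_types = c(sig = 60, noise = 60),
                     n_genes = 150, n_age_genes = 25, age_effect_log2fc = 2,
                     dropout_rate = 0.1, subject_sd = 0.05,
                     frac_nonpregnant = 0, age_genes_disjoint_by_type = FALSE,
                     seed = 41)
  co <- generateCohort(spec)
  ds <- logNormalize(co$dataset)
  ## planted ISG-like genes respond to age in every type; zero them back out
  ## in the "noise" type by regenerating that type from a no-signal cohort
  spec0 <- cohortSpec(n_subjects = 40, cell_types = c(noise = 60),
                      n_genes = 150, n_age_genes = 0, dropout_rate = 0.1,
                      subject_sd = 0.05, frac_nonpregnant = 0, seed = 42)
  ds0 <- logNormalize(generateCohort(spec0)$dataset)
  subsets <- list(sig = ds[, cellType(ds) == "sig"], noise = ds0)
  cfg <- clockConfig(n_candidates = 5, cv_folds = 3, seed = 43)
  res <- runClockAllTypes(subsets, cfg)
  expect_setequal(res$summary$cell_type, c("sig", "noise"))
  r_sig <- res$summary$R[res$summary$cell_type == "sig"]
  r_noise <- res$summary$R[res$summary$cell_type == "noise"]
  expect_gt(r_sig, ifelse(is.na(r_noise), 0.5, r_noise))
  expect_false(res$summary$retained[res$summary$cell_type == "noise"])

  res2 <- runClockAllTypes(subsets, cfg)
  expect_identical(res$summary, res2$summary)

  expect_length(runClockAllTypes(list(), cfg)$models, 0)
})
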