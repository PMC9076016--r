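test_that("signature construction rejects malformed input", {
  expect_error(geneSignature("s", character()), "non-empty")
  expect_error(geneSignature("s", c("A", "A")), "duplicate")
  expect_error(geneSignature("s", "A", role = "nope"), "role")
  sigs <- readSignatures()
  expect_true(all(c("cytotoxicity", "apoptosis", "exhaustion", "ISG") %in%
                    names(sigs)))
  expect_length(signatureGenes(sigs$cytotoxicity), 10)
  expect_length(signatureGenes(sigs$exhaustion), 5)
})

test_that("module score is exactly zero on constant expression", {
  ds <- toy_lognorm(matrix(2.5, 60, 30))
  sc <- moduleScore(ds, geneSignature("s", sprintf("G%03d", 1:5)),
                    n_bins = 4, n_ctrl = 10, seed = 1)
  expect_equal(sc$score, rep(0, 30), tolerance = 1e-12)
})

test_that("a whole-universe signature scores near zero", {
  set.seed(8)
  ds <- toy_lognorm(matrix(rexp(400 * 300, 1), 400, 300))
  sig <- geneSignature("all", sprintf("G%03d", 1:400))
  sc <- moduleScore(ds, sig, seed = 3)
  expect_lt(mean(abs(sc$score)), 0.02)
})

test_that("a planted 1-log-unit shift separates cells by about 1", {
  set.seed(10)
  ## heterogeneous per-gene baselines so each expression bin mixes
  ## signature and non-signature genes, and a signature small enough
  ## (5% of the universe) that matched controls are mostly background
  levels <- runif(500, 0, 4)
  base <- matrix(rexp(500 * 400, 1), 500, 400) + levels
  sig_idx <- sample(500, 25)
  sig_genes <- sprintf("G%03d", sig_idx)
  half <- 1:200
  base[sig_idx, half] <- base[sig_idx, half] + 1
  ds <- toy_lognorm(base)
  sc <- moduleScore(ds, geneSignature("sig", sig_genes), seed = 4)
  diff <- mean(sc$score[half]) - mean(sc$score[-half])
  expect_lt(abs(diff - 1), 0.1)
})

test_that("module score is invariant to cell order, gene order and constant shifts", {
  set.seed(11)
  m <- matrix(rexp(120 * 80, 1), 120, 80)
  ds <- toy_lognorm(m)
  sig <- geneSignature("s", sprintf("G%03d", c(3, 17, 40, 90, 111)))
  ref <- moduleScore(ds, sig, n_bins = 10, n_ctrl = 20, seed = 7)

  perm_cells <- sample(80)
  ds_c <- toy_lognorm(m[, perm_cells])
  got_c <- moduleScore(ds_c, sig, n_bins = 10, n_ctrl = 20, seed = 7)
  expect_equal(got_c$score[order(perm_cells)], ref$score, tolerance = 1e-12)

  perm_genes <- sample(120)
  ds_g <- toy_lognorm(m[perm_genes, ],
                      gene_names = sprintf("G%03d", perm_genes))
  got_g <- moduleScore(ds_g, sig, n_bins = 10, n_ctrl = 20, seed = 7)
  expect_equal(got_g$score, ref$score, tolerance = 1e-12)

  ds_shift <- toy_lognorm(m + 3)
  got_s <- moduleScore(ds_shift, sig, n_bins = 10, n_ctrl = 20, seed = 7)
  expect_equal(got_s$score, ref$score, tolerance = 1e-12)
})

test_that("unmatched signature genes warn; fully unmatched errors", {
  ds <- toy_lognorm(matrix(1:20 / 3, 20, 4))
  expect_warning(
    sc <- moduleScore(ds, geneSignature("s", c("G001", "NOPE")),
                      n_bins = 4, n_ctrl = 5, seed = 1),
    "dropped")
  expect_equal(nrow(sc), 4)
  expect_error(moduleScore(ds, geneSignature("s", "NOPE"), n_bins = 4,
                           n_ctrl = 5, seed = 1), "no signature gene")
})

test_that("rank-sum comparisons: degenerate, exact and enumerated cases", {
  sc <- data.frame(score = c(1, 2, 3, 1, 2, 3),
                   stage = rep(c("first", "second"), each = 3))
  out <- stageCompare(sc)
  expect_equal(out$p, 1)
  expect_identical(out$stars, "ns")

  sc2 <- data.frame(score = c(1, 2, 3, 4, 5, 6),
                    stage = rep(c("first", "second"), each = 3))
  out2 <- stageCompare(sc2)
  ## oracle: enumerate all 20 equally likely group assignments
  vals <- 1:6
  splits <- utils::combn(6, 3, simplify = FALSE)
  W_all <- vapply(splits, function(s) sum(rank(vals)[s]) - 6, numeric(1))
  W_obs <- sum(rank(vals)[1:3]) - 6
  p_exact <- mean(abs(W_all - mean(W_all)) >= abs(W_obs - mean(W_all)))
  expect_equal(p_exact, 0.1)
  expect_equal(out2$p, p_exact, tolerance = 1e-12)

  ## monotone-transform invariance of the p-value
  sc3 <- sc2; sc3$score <- exp(sc3$score)
  expect_equal(stageCompare(sc3)$p, out2$p, tolerance = 1e-12)

  expect_error(stageCompare(sc2, pairs = list(c("first", "third"))), "empty")
})

test_that("stage comparison can use subjects as the unit", {
  sc <- data.frame(score = c(1, 2, 10, 1, 5, 6),
                   stage = rep(c("first", "second"), each = 3),
                   subject_id = c("a", "a", "b", "c", "c", "d"))
  out <- stageCompare(sc, unit = "subject")
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 1)
})

test_that("gene-age correlation: perfect, degenerate and guarded cases", {
  ## gene whose weekly mean equals the week number
  weeks <- rep(c(10, 20, 30, 40), each = 5)
  m <- rbind(rep(weeks, 1), rep(1, 20))
  ds <- toy_lognorm(m, ga_days = weeks * 7,
                    subject = sprintf("S%02d", seq_along(weeks)))
  out <- geneAgeCorrelation(ds, c("G001", "G002"))
  expect_equal(out$r[out$gene == "G001"], 1, tolerance = 1e-12)
  expect_lt(out$p[out$gene == "G001"], 1e-10)
  expect_true(is.na(out$r[out$gene == "G002"]))
  expect_identical(out$note[out$gene == "G002"], "zero variance")

  ds2 <- toy_lognorm(m[, 1:10], ga_days = weeks[1:10] * 7)
  expect_error(geneAgeCorrelation(ds2, "G001"), "3 distinct")
})

test_that("planted age genes show positive weekly-mean correlations", {
  spec <- cohortSpec(n_subjects = 100, cell_types = c(T = 30), n_genes = 60,
                     n_age_genes = 20, age_effect_log2fc = 1,
                     subject_sd = 0.05, frac_nonpregnant = 0, seed = 14)
  co <- generateCohort(spec)
  ds <- logNormalize(co$dataset)
  out <- geneAgeCorrelation(ds, rownames(ds))
  planted <- out[out$gene %in% co$truth@ageGenes, ]
  expect_gte(mean(planted$r > 0), 0.95)
  expect_lt(mean(abs(out$r[!out$gene %in% co$truth@ageGenes]), na.rm = TRUE),
            mean(planted$r))
})

test_that("differential expression: identity, antisymmetry and marker mode", {
  set.seed(12)
  m <- matrix(rexp(100 * 60, 1), 100, 60)
  ds <- toy_lognorm(m)
  ids <- colnames(ds)
  same <- differentialExpression(ds, ids[1:30], ids[1:30])
  expect_equal(sum(same$significant), 0)
  expect_equal(same$log2fc, rep(0, 100), tolerance = 1e-12)

  ab <- differentialExpression(ds, ids[1:30], ids[31:60])
  ba <- differentialExpression(ds, ids[31:60], ids[1:30])
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$p_adj, p.adjust(ab$p, "BH"), tolerance = 1e-12)

  mk <- differentialExpression(ds, ids[1:30], ids[31:60], marker_mode = TRUE)
  expect_true(all(mk$log2fc[mk$significant] > 0))
  expect_true(all(pmax(mk$pct_group1, mk$pct_group2) >= 0.25))
})

test_that("planted fold changes are recovered at the standard thresholds", {
  set.seed(13)
  n_genes <- 300; n_cells <- 400
  planted <- sprintf("G%03d", 1:30)
  ## planted genes are expressed (mu >= 1): a fold change on an almost
  ## never detected gene is not recoverable by any test. Half the
  ## planted genes double, half halve, keeping library sizes balanced.
  mu <- c(runif(30, 1, 4), rexp(n_genes - 30, 1 / 2))
  fc <- c(rep(2, 15), rep(0.5, 15))
  cnt <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 2), n_genes)
  cnt[1:30, 201:400] <- matrix(
    rnbinom(30 * 200, mu = fc * mu[1:30], size = 2), 30)
  ds <- logNormalize(toy_cohort(cnt))
  ids <- colnames(ds)
  de <- differentialExpression(ds, ids[201:400], ids[1:200])
  called <- de$gene[de$significant]
  expect_gte(mean(planted %in% called), 0.9)
  expect_lte(mean(!(called %in% planted)), 0.1)
  dirs <- de$direction[match(planted, de$gene)]
  expect_true(all(dirs[1:15] == "up") && all(dirs[16:30] == "down"))
})
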