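#' Specify a synthetic single-cell pregnancy cohort
#'
#' Defines the statistical structure of a simulated PBMC cohort: subjects
#' spanning a gestational-age range plus optional non-pregnant controls,
#' cell types of unequal abundance, negative-binomial counts with
#' subject-level random effects and Bernoulli dropout, and a planted
#' minority of genes whose log-mean increases linearly with gestational
#' age (ISG-like behaviour). Defaults emulate a cohort of 136 donors
#' (weeks 6-40 plus a small non-pregnant control group) at a desk-scale
#' gene count.
#'
#' @param n_subjects total number of subjects (pregnant + controls).
#' @param gestational_age_range_days closed integer interval of pregnant
#'   ages in days, default `c(42L, 280L)` (weeks 6-40).
#' @param frac_nonpregnant fraction of subjects that are non-pregnant
#'   controls (gestational age 0), in `[0, 1)`.
#' @param cell_types named numeric vector: mean cells per subject for each
#'   cell type.
#' @param n_genes number of genes (including mitochondrial genes).
#' @param n_age_genes number of planted age-dependent genes
#'   (`<= n_genes`).
#' @param age_effect_log2fc maximum log2 fold change of a planted gene
#'   across the gestational-age range.
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param dropout_rate probability that any count is zeroed
#'   (independent Bernoulli dropout), in `[0, 1)`.
#' @param subject_sd standard deviation of the subject-level log-scale
#'   random effect.
#' @param type_effect_sd standard deviation of the per-gene log-scale
#'   cell-type effect (0 gives identical baselines across types).
#' @param mito_frac_mean target mean mitochondrial count fraction per cell.
#' @param n_mito_genes number of genes named with the `"MT-"` prefix.
#' @param baseline_log_mu,baseline_log_sd log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param age_genes_disjoint_by_type if `TRUE`, the planted genes are
#'   partitioned across cell types and each planted gene responds to age
#'   in its own cell type only.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return a validated list of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohortSpec(n_subjects = 10, cell_types = c(NK = 20),
#'                    n_genes = 100, n_age_genes = 5, seed = 1)
#' cohort <- generateCohort(spec)
cohortSpec <- function(n_subjects = 136L,
                       gestational_age_range_days = c(42L, 280L),
                       frac_nonpregnant = 5 / 136,
                       cell_types = c("CD4+ naive T" = 60, "CD8+ naive T" = 40,
                                      "NK" = 30, "monocyte" = 50,
                                      "naive B" = 15, "dnT" = 8),
                       n_genes = 1000L,
                       n_age_genes = 50L,
                       age_effect_log2fc = 2,
                       dispersion = 2,
                       dropout_rate = 0.3,
                       subject_sd = 0.15,
                       type_effect_sd = 0.5,
                       mito_frac_mean = 0.03,
                       n_mito_genes = 10L,
                       baseline_log_mu = log(0.5),
                       baseline_log_sd = 1,
                       age_genes_disjoint_by_type = FALSE,
                       seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               gestational_age_range_days = as.integer(gestational_age_range_days),
               frac_nonpregnant = frac_nonpregnant,
               cell_types = cell_types,
               n_genes = as.integer(n_genes),
               n_age_genes = as.integer(n_age_genes),
               age_effect_log2fc = age_effect_log2fc,
               dispersion = dispersion,
               dropout_rate = dropout_rate,
               subject_sd = subject_sd,
               type_effect_sd = type_effect_sd,
               mito_frac_mean = mito_frac_mean,
               n_mito_genes = as.integer(n_mito_genes),
               baseline_log_mu = baseline_log_mu,
               baseline_log_sd = baseline_log_sd,
               age_genes_disjoint_by_type = isTRUE(age_genes_disjoint_by_type),
               seed = as.integer(seed))
  .validate_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

.validate_spec <- function(s) {
  stopifnot(s$n_subjects >= 1L,
            length(s$gestational_age_range_days) == 2L,
            s$gestational_age_range_days[1] >= 1L,
            diff(s$gestational_age_range_days) >= 0L,
            s$frac_nonpregnant >= 0, s$frac_nonpregnant < 1,
            length(s$cell_types) >= 1L, !is.null(names(s$cell_types)),
            all(s$cell_types > 0),
            s$n_genes >= 1L, s$n_age_genes >= 0L,
            s$age_effect_log2fc > 0, s$dispersion > 0,
            s$dropout_rate >= 0, s$dropout_rate < 1,
            s$subject_sd >= 0, s$type_effect_sd >= 0,
            s$mito_frac_mean >= 0, s$mito_frac_mean < 1,
            s$n_mito_genes >= 0L, s$n_mito_genes < s$n_genes)
  if (s$n_age_genes > s$n_genes)
    stop("invalid spec: n_age_genes exceeds n_genes")
  if (s$n_age_genes > s$n_genes - s$n_mito_genes)
    stop("invalid spec: n_age_genes exceeds the non-mitochondrial gene count")
  invisible(TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws counts per gene and cell from a negative binomial whose log mean
#' combines a per-gene baseline, a per-cell-type effect, a subject-level
#' random effect and, for planted genes, a term linear in gestational age
#' scaled so the extreme ages of the range differ by
#' `age_effect_log2fc` log2 units. Independent Bernoulli dropout is
#' applied afterwards. Mitochondrial gene means are calibrated so the
#' expected mitochondrial fraction matches `mito_frac_mean`. Output is
#' byte-identical under a fixed spec.
#'
#' @param spec a [cohortSpec()].
#' @return list with `dataset` (a [CohortExperiment-class], counts layer)
#'   and `truth` (a [CohortTruth-class] recording planted genes, slopes
#'   and subject ages).
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohortSpec, spec)
  .validate_spec(spec)
  .with_seed(spec$seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(s) {
  n_mt <- s$n_mito_genes
  n_reg <- s$n_genes - n_mt
  genes <- c(sprintf("G%04d", seq_len(n_reg)),
             if (n_mt > 0) sprintf("MT-%d", seq_len(n_mt)))

  n_np <- round(s$n_subjects * s$frac_nonpregnant)
  n_pg <- s$n_subjects - n_np
  subjects <- sprintf("S%03d", seq_len(s$n_subjects))
  rng <- s$gestational_age_range_days
  ages <- c(sample(seq(rng[1], rng[2]), n_pg, replace = TRUE),
            rep(0L, n_np))
  names(ages) <- subjects

  types <- names(s$cell_types)
  ## per-gene baseline means; mitochondrial total calibrated to the target
  ## count fraction r via  mito_total = r / (1 - r) * regular_total
  base <- exp(rnorm(n_reg, s$baseline_log_mu, s$baseline_log_sd))
  if (n_mt > 0) {
    r <- s$mito_frac_mean
    mt_total <- if (r > 0) r / (1 - r) * sum(base) else 0
    share <- exp(rnorm(n_mt, 0, 0.3))
    base <- c(base, mt_total * share / sum(share))
  }
  type_fx <- matrix(exp(rnorm(s$n_genes * length(types), 0, s$type_effect_sd)),
                    nrow = s$n_genes, ncol = length(types),
                    dimnames = list(genes, types))
  base_means <- base * type_fx

  ## planted age genes: positive log2-per-day slope reaching age_effect_log2fc
  ## at the far end of the range
  age_genes <- if (s$n_age_genes > 0) sort(sample(genes[seq_len(n_reg)], s$n_age_genes)) else character()
  span <- max(1L, rng[2] - rng[1])
  slopes <- setNames(numeric(s$n_genes), genes)
  slopes[age_genes] <- s$age_effect_log2fc / span
  age_by_type <- list()
  if (s$age_genes_disjoint_by_type && length(age_genes)) {
    idx <- rep(seq_along(types), length.out = length(age_genes))
    age_by_type <- split(age_genes, types[idx])
  }

  subj_fx <- setNames(rnorm(s$n_subjects, 0, s$subject_sd), subjects)
  blocks <- list(); metas <- list(); k <- 0L
  for (si in subjects) {
    age <- ages[[si]]
    age_term <- if (age > 0) 2^(slopes * (age - rng[1])) else rep(1, s$n_genes)
    for (ty in types) {
      n_cells <- rpois(1, s$cell_types[[ty]])
      if (n_cells == 0) next
      mu <- base_means[, ty] * exp(subj_fx[[si]])
      if (length(age_by_type)) {
        mu2 <- mu
        g_ty <- age_by_type[[ty]]
        if (length(g_ty) && age > 0)
          mu2[g_ty] <- mu[g_ty] * 2^(slopes[g_ty] * (age - rng[1]))
        mu <- mu2
      } else {
        mu <- mu * age_term
      }
      cnt <- if (is.finite(s$dispersion)) {
        matrix(rnbinom(s$n_genes * n_cells, mu = mu, size = s$dispersion),
               nrow = s$n_genes)
      } else {
        matrix(rpois(s$n_genes * n_cells, lambda = mu), nrow = s$n_genes)
      }
      if (s$dropout_rate > 0)
        cnt <- cnt * matrix(rbinom(length(cnt), 1, 1 - s$dropout_rate),
                            nrow = s$n_genes)
      rownames(cnt) <- genes
      k <- k + 1L
      blocks[[k]] <- as(as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")
      metas[[k]] <- data.frame(subject_id = si, cell_type = ty,
                               ga_days = age, stringsAsFactors = FALSE)[rep(1, n_cells), ]
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  meta$cell_id <- sprintf("C%06d", seq_len(nrow(meta)))
  rownames(meta) <- NULL
  ds <- CohortExperiment(counts, meta)
  truth <- new("CohortTruth", ageGenes = age_genes, slopes = slopes,
               subjectAges = ages, baseMeans = base_means,
               ageGenesByType = age_by_type)
  list(dataset = ds, truth = truth)
}

#' Write a cohort to a Matrix Market + TSV directory
#'
#' Writes `matrix.mtx` (cells x genes, integer counts, orientation noted
#' in a header comment), `genes.tsv` (one symbol per line) and
#' `cells.tsv` (`cell_id`, `subject_id`, `cell_type`, `ga_days`,
#' `ga_weeks`, `stage`). Round-trips losslessly through [readCohort()].
#'
#' @param ds a [CohortExperiment-class] carrying a counts layer.
#' @param path output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(ds, path) {
  stopifnot(is(ds, "CohortExperiment"))
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", path)
  mtx <- file.path(path, "matrix.mtx")
  Matrix::writeMM(Matrix::t(assay(ds, "counts")), mtx)
  lines <- readLines(mtx)
  writeLines(c(lines[1], "% orientation: rows are cells, columns are genes",
               lines[-1]), mtx)
  writeLines(rownames(ds), file.path(path, "genes.tsv"))
  cd <- as.data.frame(colData(ds))[, .required_cols, drop = FALSE]
  write.table(cd, file.path(path, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(path, c("matrix.mtx", "genes.tsv", "cells.tsv")))
}

#' Read a cohort written by [writeCohort()]
#'
#' @param path directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a [CohortExperiment-class] with a counts layer.
#' @export
readCohort <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", path)
  m <- Matrix::t(Matrix::readMM(mtx))          # file is cells x genes
  genes <- readLines(file.path(path, "genes.tsv"))
  meta <- read.delim(file.path(path, "cells.tsv"), stringsAsFactors = FALSE,
                     colClasses = c(cell_id = "character",
                                    subject_id = "character"))
  rownames(m) <- genes
  CohortExperiment(m, meta)
}
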