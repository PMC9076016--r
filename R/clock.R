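#' Build pseudo-cells by per-gene medians over same-subject groups
#'
#' Within each subject, cells are randomly permuted (seeded), partitioned
#' into consecutive groups of `group_size`, and each group is collapsed
#' to its per-gene median (midpoint convention for even groups).
#' Leftover cells that do not fill a group are discarded, so a subject
#' with n cells yields `floor(n / group_size)` pseudo-cells — groups
#' never mix subjects.
#'
#' @param ds a [CohortExperiment-class] restricted to a single cell type,
#'   normalized layer active.
#' @param group_size cells per pseudo-cell (default 10).
#' @param seed integer seed for the within-subject permutation.
#' @return a [PseudoCellSet-class] (pseudo-cells x genes).
#' @export
makePseudoCells <- function(ds, group_size = 10L, seed = 1L) {
  stopifnot(is(ds, "CohortExperiment"))
  if (group_size <= 0) stop("group_size must be >= 1")
  types <- unique(cellType(ds))
  if (length(types) != 1L)
    stop("makePseudoCells expects a single cell type; found ", length(types))
  m <- .active_assay(ds)
  subj <- subjectID(ds)
  age <- gaDays(ds)
  ord <- .with_seed(seed, {
    unlist(lapply(sort(unique(subj)), function(s) {
      idx <- which(subj == s)
      idx[sample.int(length(idx))]
    }))
  })
  rows <- list(); meta <- list(); k <- 0L
  for (s in sort(unique(subj))) {
    idx <- ord[subj[ord] == s]
    n_grp <- floor(length(idx) / group_size)
    if (n_grp == 0) next
    used <- idx[seq_len(n_grp * group_size)]
    dense <- as.matrix(m[, used, drop = FALSE])
    for (g in seq_len(n_grp)) {
      cols <- ((g - 1L) * group_size + 1L):(g * group_size)
      k <- k + 1L
      rows[[k]] <- matrixStats::rowMedians(dense[, cols, drop = FALSE])
      md <- data.frame(subject_id = s, ga_days = age[idx[1]],
                       cell_type = types, group_index = g,
                       stringsAsFactors = FALSE)
      md$cells <- I(list(colnames(ds)[used[cols]]))  # group membership, for audits
      meta[[k]] <- md
    }
  }
  if (k == 0L)
    stop("no subject has at least group_size cells")
  ex <- do.call(rbind, rows)
  colnames(ex) <- rownames(ds)
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  new("PseudoCellSet", exprs = ex, meta = md,
      groupSize = as.integer(group_size), layerTag = layerTag(ds))
}

#' Stratified subject-level train/test split
#'
#' Pregnant subjects are stratified by pregnancy period (early/middle/
#' late) and split within each stratum at the given train ratio. No
#' subject can appear on both sides; a single-subject stratum is
#' assigned to training with a warning. Non-pregnant subjects are
#' excluded: the clock predicts the age of normal pregnancy.
#'
#' @param ds a [CohortExperiment-class] (or a [PseudoCellSet-class]).
#' @param ratio train fraction, default 0.7.
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
splitSubjects <- function(ds, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  if (is(ds, "PseudoCellSet")) {
    subj <- ds@meta$subject_id; age <- ds@meta$ga_days
  } else {
    subj <- subjectID(ds); age <- gaDays(ds)
  }
  tab <- unique(data.frame(subject_id = subj, ga_days = age,
                           stringsAsFactors = FALSE))
  tab$period <- periodFromWeeks(floor(tab$ga_days / 7))
  tab <- tab[!is.na(tab$period), , drop = FALSE]
  if (!nrow(tab)) stop("no pregnant subjects to split")
  tab <- tab[order(tab$subject_id), ]
  assign_side <- .with_seed(seed, {
    side <- character(nrow(tab))
    for (per in unique(tab$period)) {
      idx <- which(tab$period == per)
      if (length(idx) == 1L) {
        warning("stratum '", per, "' has a single subject; assigned to train")
        side[idx] <- "train"
        next
      }
      n_train <- max(1L, round(ratio * length(idx)))
      if (n_train == length(idx)) n_train <- length(idx) - 1L
      sh <- idx[sample.int(length(idx))]
      side[sh[seq_len(n_train)]] <- "train"
      side[sh[-seq_len(n_train)]] <- "test"
    }
    side
  })
  tab$side <- assign_side
  new("SplitPlan",
      trainSubjects = tab$subject_id[tab$side == "train"],
      testSubjects = tab$subject_id[tab$side == "test"],
      ratio = ratio, strata = tab, seed = as.integer(seed))
}

#' Subset a PseudoCellSet to a set of subjects (or genes)
#'
#' @param pc a [PseudoCellSet-class].
#' @param subjects subject ids to keep (`NULL` keeps all).
#' @param genes gene names to keep, in the given order (`NULL` keeps all).
#' @return the subset `PseudoCellSet`.
#' @export
subsetPseudoCells <- function(pc, subjects = NULL, genes = NULL) {
  stopifnot(is(pc, "PseudoCellSet"))
  if (!is.null(subjects)) {
    keep <- pc@meta$subject_id %in% subjects
    pc@exprs <- pc@exprs[keep, , drop = FALSE]
    pc@meta <- pc@meta[keep, , drop = FALSE]
  }
  if (!is.null(genes))
    pc@exprs <- pc@exprs[, genes, drop = FALSE]
  rownames(pc@meta) <- NULL
  pc
}

#' LASSO selection of gestational-age-relevant genes
#'
#' Fits an L1-penalized linear regression of gestational age (days) on
#' the scaled pseudo-cell matrix at a fixed penalty (the `1/(2n)`
#' residual-sum-of-squares parameterization, so the penalty is directly
#' comparable across cohort sizes) and returns the genes with nonzero
#' coefficients ordered by decreasing |coefficient|. If shrinkage leaves
#' no gene, a fallback engages with a warning: the 50 genes most
#' correlated (absolute Pearson) with age.
#'
#' @param pc a scaled [PseudoCellSet-class] of training pseudo-cells.
#' @param penalty L1 penalty, default 0.1.
#' @param fallback_n genes returned by the correlation fallback.
#' @return character vector of selected genes (attribute `fallback`
#'   marks an engaged fallback; attribute `coefficients` carries the
#'   fitted values).
#' @export
selectGenesLasso <- function(pc, penalty = 0.1, fallback_n = 50L) {
  stopifnot(is(pc, "PseudoCellSet"), penalty > 0)
  x <- pc@exprs
  y <- pc@meta$ga_days
  if (nrow(x) < 2) stop("need at least 2 pseudo-cells")
  lambdas <- sort(unique(c(penalty * c(50, 20, 10, 5, 2, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambdas, standardize = FALSE)
  cf <- as.numeric(coef(fit, s = penalty, exact = FALSE))[-1]
  names(cf) <- colnames(x)
  nz <- cf[cf != 0]
  if (!length(nz)) {
    warning("LASSO selected no gene at penalty ", penalty,
            "; falling back to top-", fallback_n, " age-correlated genes")
    if (sd(y) == 0) stop("cannot rank genes: constant target")
    cors <- abs(apply(x, 2, function(col) {
      if (sd(col) == 0) 0 else cor(col, y)
    }))
    sel <- names(sort(cors, decreasing = TRUE))[seq_len(min(fallback_n, ncol(x)))]
    attr(sel, "fallback") <- TRUE
    return(sel)
  }
  nz <- nz[!duplicated(names(nz))]
  sel <- names(sort(abs(nz), decreasing = TRUE))
  attr(sel, "fallback") <- FALSE
  attr(sel, "coefficients") <- nz[sel]
  sel
}

## Random-search hyperparameter space of the random-forest regressor:
## trees 100-300, depth unlimited or 5-30, min node size 1-10, feature
## fraction around the sqrt(p)-to-p/4 conventions, bootstrap fraction
## 0.5-1. The ranges keep a full 25 x 5-fold tune on ~800 pseudo-cells
## x ~700 genes within minutes on one CPU.
.sample_candidates <- function(n, p) {
  data.frame(
    num_trees = sample(c(100L, 200L, 300L), n, replace = TRUE),
    max_depth = sample(c(0L, seq(5L, 30L, by = 5L)), n, replace = TRUE),
    min_node_size = sample(1:10, n, replace = TRUE),
    mtry = pmax(1L, floor(runif(n, 0.05, 0.20) * p)),
    sample_fraction = runif(n, 0.5, 1.0))
}

.fit_ranger <- function(x, y, hp, seed) {
  ranger::ranger(x = x, y = y,
                 num.trees = hp$num_trees,
                 max.depth = hp$max_depth,
                 min.node.size = hp$min_node_size,
                 mtry = min(hp$mtry, ncol(x)),
                 sample.fraction = hp$sample_fraction %||% 1,
                 seed = seed, num.threads = 1L,
                 oob.error = FALSE, verbose = FALSE)
}

#' Tune and train the random-forest gestational-age regressor
#'
#' Random search over the forest hyperparameter space (trees 100-1000,
#' max depth unlimited or 5-30, min node size 1-10, feature fraction
#' 0.1-1.0): each candidate is scored by mean RMSE over `cv_folds`-fold
#' cross-validation on the training pseudo-cells, the best candidate is
#' refit on the whole training set, and the per-candidate CV table is
#' retained in the model.
#'
#' @param pc scaled training [PseudoCellSet-class].
#' @param genes selected genes (from [selectGenesLasso()]).
#' @param scaler the training scaler from [scaleGenes()], stored for test
#'   transformation.
#' @param n_candidates random-search draws (default 25).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed integer seed governing the search, folds and forests.
#' @param lasso_penalty recorded penalty (provenance only).
#' @return a [ClockModel-class].
#' @export
tuneAndTrain <- function(pc, genes, scaler = NULL, n_candidates = 25L,
                         cv_folds = 5L, seed = 1L, lasso_penalty = 0.1) {
  stopifnot(is(pc, "PseudoCellSet"), length(genes) >= 1, cv_folds >= 2)
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  x <- pc@exprs[, genes, drop = FALSE]
  y <- pc@meta$ga_days
  res <- .with_seed(seed, {
    cand <- .sample_candidates(n_candidates, ncol(x))
    folds <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    rmse <- sapply(seq_len(n_candidates), function(i) {
      errs <- sapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
        fit <- .fit_ranger(x[tr, , drop = FALSE], y[tr], cand[i, ],
                           seed = .derive_seed(seed, i * 10L + f))
        pred <- predict(fit, data = x[!tr, , drop = FALSE],
                        num.threads = 1L)$predictions
        sqrt(mean((pred - y[!tr])^2))
      })
      mean(errs, na.rm = TRUE)
    })
    list(cand = cand, rmse = rmse)
  })
  cv <- cbind(res$cand, cv_rmse = res$rmse)
  best <- which.min(res$rmse)
  hp <- as.list(res$cand[best, ])
  forest <- .fit_ranger(x, y, res$cand[best, ], seed = .derive_seed(seed, 999L))
  new("ClockModel",
      cellType = as.character(pc@meta$cell_type[1]),
      selectedGenes = colnames(x),
      scaler = scaler %||% list(),
      lassoPenalty = lasso_penalty,
      forest = forest,
      hyperParams = hp,
      cvSummary = cv,
      trainingData = x,
      trainingAges = as.numeric(y),
      seed = as.integer(seed),
      provenance = list(
        n_candidates = n_candidates, cv_folds = cv_folds,
        data_fingerprint = .fingerprint(c(dim(x), sum(x), sum(y)))))
}

## Transform a pseudo-cell set into a model's feature space: apply the
## stored training scaler when the set is not already scaled, then
## restrict to the selected genes.
.model_space <- function(model, pc) {
  stopifnot(is(pc, "PseudoCellSet"))
  if (pc@layerTag != "scaled") {
    if (!length(model@scaler))
      stop("model carries no scaler and pseudo-cells are unscaled")
    pc <- applyScaler(pc, model@scaler)
  }
  miss <- setdiff(model@selectedGenes, colnames(pc@exprs))
  if (length(miss))
    stop("pseudo-cells lack model genes: ", paste(head(miss, 3), collapse = ", "))
  subsetPseudoCells(pc, genes = model@selectedGenes)
}

#' Subject-level prediction and evaluation
#'
#' Predicts every test pseudo-cell with the fitted forest, averages
#' predictions within subject, and scores the subject-level predictions
#' against true gestational age with Pearson's R (two-sided t-test,
#' n - 2 df), RMSE in days, and per-period (early/middle/late) metrics.
#' A model is retained when `R >= retention_R`. With fewer than 3 test
#' subjects, or constant predictions, correlation metrics are reported
#' as `NA` while predictions are still emitted.
#'
#' @param model a [ClockModel-class].
#' @param pc test pseudo-cells (scaled or not; unscaled sets are
#'   transformed with the model's stored training scaler).
#' @param retention_R retention threshold on R (default 0.8).
#' @return a [ClockEvaluation-class].
#' @export
predictSubjects <- function(model, pc, retention_R = 0.8) {
  stopifnot(is(model, "ClockModel"))
  pc <- .model_space(model, pc)
  pred <- predict(model@forest, data = pc@exprs,
                  num.threads = 1L)$predictions
  subj <- pc@meta$subject_id
  per_subj <- data.frame(
    subject_id = sort(unique(subj)),
    stringsAsFactors = FALSE)
  per_subj$ga_true_days <- vapply(per_subj$subject_id, function(s)
    as.numeric(pc@meta$ga_days[match(s, subj)]), numeric(1))
  per_subj$ga_pred_days <- vapply(per_subj$subject_id, function(s)
    mean(pred[subj == s]), numeric(1))
  per_subj$period <- periodFromWeeks(floor(per_subj$ga_true_days / 7))
  metrics <- .subject_metrics(per_subj$ga_true_days, per_subj$ga_pred_days)
  per_period <- do.call(rbind, lapply(c("early", "middle", "late"), function(p) {
    sub <- per_subj[per_subj$period %in% p, , drop = FALSE]
    mm <- .subject_metrics(sub$ga_true_days, sub$ga_pred_days)
    data.frame(period = p, n_subjects = nrow(sub), R = mm$R, p = mm$p,
               rmse = mm$rmse, stringsAsFactors = FALSE)
  }))
  new("ClockEvaluation", subjects = per_subj,
      R = metrics$R, p = metrics$p, rmse = metrics$rmse,
      retained = isTRUE(metrics$R >= retention_R),
      perPeriod = per_period)
}

.subject_metrics <- function(truth, pred) {
  if (length(truth) < 3 || sd(pred) == 0 || sd(truth) == 0)
    return(list(R = NA_real_, p = NA_real_,
                rmse = if (length(truth)) sqrt(mean((pred - truth)^2)) else NA_real_))
  ht <- cor.test(truth, pred, method = "pearson")
  list(R = unname(ht$estimate), p = ht$p.value,
       rmse = sqrt(mean((pred - truth)^2)))
}

#' Run the full clock pipeline for every cell type
#'
#' For each per-type dataset (from [subsetCellTypes()]): split subjects,
#' build pseudo-cells within each side, scale on training pseudo-cells,
#' select genes by LASSO, tune and train the forest, and evaluate on the
#' held-out subjects. Types failing a precondition are skipped with a
#' recorded reason rather than aborting the run.
#'
#' @param datasets named list of single-type [CohortExperiment-class]
#'   objects with a normalized active layer.
#' @param config list of clock parameters; see [clockConfig()].
#' @return list with `models`, `evaluations`, `summary` (data.frame
#'   ranked by R) and `skipped`.
#' @export
runClockAllTypes <- function(datasets, config = clockConfig()) {
  models <- list(); evals <- list(); skipped <- list()
  for (ty in names(datasets)) {
    res <- tryCatch(
      .run_clock_one(datasets[[ty]], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[ty]] <- conditionMessage(res)
      next
    }
    models[[ty]] <- res$model
    evals[[ty]] <- res$evaluation
  }
  summ <- do.call(rbind, lapply(names(evals), function(ty) {
    ev <- evals[[ty]]
    data.frame(cell_type = ty, n_genes = length(selectedGenes(models[[ty]])),
               n_test_subjects = nrow(ev@subjects), R = ev@R, p = ev@p,
               rmse = ev@rmse, retained = ev@retained,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(summ)) summ <- summ[order(-ifelse(is.na(summ$R), -Inf, summ$R)), ]
  rownames(summ) <- NULL
  list(models = models, evaluations = evals, summary = summ,
       skipped = skipped)
}

#' Clock pipeline parameters
#'
#' @param group_size cells per pseudo-cell (default 10).
#' @param ratio train fraction of the subject split (default 0.7).
#' @param lasso_penalty LASSO penalty (default 0.1).
#' @param n_candidates random-search draws (default 25).
#' @param cv_folds cross-validation folds (default 5).
#' @param retention_R retention threshold on held-out R (default 0.8).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `clock_config`.
#' @export
clockConfig <- function(group_size = 10L, ratio = 0.7, lasso_penalty = 0.1,
                        n_candidates = 25L, cv_folds = 5L, retention_R = 0.8,
                        seed = 1L) {
  structure(list(group_size = as.integer(group_size), ratio = ratio,
                 lasso_penalty = lasso_penalty,
                 n_candidates = as.integer(n_candidates),
                 cv_folds = as.integer(cv_folds), retention_R = retention_R,
                 seed = as.integer(seed)),
            class = "clock_config")
}

.run_clock_one <- function(ds, config) {
  ## split first, then pseudo-cells within each side: no group can mix
  ## train/test information
  plan <- splitSubjects(ds, ratio = config$ratio,
                        seed = .derive_seed(config$seed, 1L))
  preg <- subjectID(ds) %in% c(plan@trainSubjects, plan@testSubjects)
  ds <- ds[, preg]
  ds_train <- ds[, subjectID(ds) %in% plan@trainSubjects]
  ds_test <- ds[, subjectID(ds) %in% plan@testSubjects]
  pc_train <- makePseudoCells(ds_train, group_size = config$group_size,
                              seed = .derive_seed(config$seed, 2L))
  pc_test <- makePseudoCells(ds_test, group_size = config$group_size,
                             seed = .derive_seed(config$seed, 3L))
  sc <- scaleGenes(pc_train)
  genes <- selectGenesLasso(sc$data, penalty = config$lasso_penalty)
  model <- tuneAndTrain(sc$data, genes, scaler = sc$scaler,
                        n_candidates = config$n_candidates,
                        cv_folds = config$cv_folds,
                        seed = .derive_seed(config$seed, 4L),
                        lasso_penalty = config$lasso_penalty)
  model@provenance$split <- list(train = plan@trainSubjects,
                                 test = plan@testSubjects)
  model@provenance$lasso_fallback <- isTRUE(attr(genes, "fallback"))
  evaluation <- predictSubjects(model, pc_test,
                                retention_R = config$retention_R)
  list(model = model, evaluation = evaluation, plan = plan)
}
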