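## Flatten a ranger regression forest into the matrix layout the C++
## Shapley kernel expects (see src/treeshap.cpp).
.flatten_forest <- function(forest) {
  stopifnot(inherits(forest, "ranger"))
  lapply(seq_len(forest$num.trees), function(ti) {
    ti_df <- ranger::treeInfo(forest, ti)
    cbind(left = ifelse(is.na(ti_df$leftChild), -1, ti_df$leftChild),
          right = ifelse(is.na(ti_df$rightChild), -1, ti_df$rightChild),
          feature = ifelse(is.na(ti_df$splitvarID), -1, ti_df$splitvarID),
          threshold = ifelse(is.na(ti_df$splitval), 0, ti_df$splitval),
          value = ifelse(is.na(ti_df$prediction), 0, ti_df$prediction))
  })
}

#' Per-instance Shapley attributions of a clock model
#'
#' Computes exact tree-path Shapley values of the fitted random forest
#' for every pseudo-cell: per-gene additive attributions (in days) that
#' sum, together with the base value, to the model's prediction for that
#' instance (additivity holds to floating precision). Node covers are
#' taken from the model's training pseudo-cells.
#'
#' @param model a [ClockModel-class].
#' @param pc pseudo-cells to attribute (scaled or not); defaults to the
#'   model's training set.
#' @return list with `phi` (instances x genes matrix, days), `base`
#'   (scalar expected prediction) and `pred` (per-instance forest
#'   predictions, equal to `rowSums(phi) + base`).
#' @export
shapValues <- function(model, pc = NULL) {
  stopifnot(is(model, "ClockModel"))
  x <- if (is.null(pc)) model@trainingData else .model_space(model, pc)@exprs
  if (!identical(colnames(x), model@selectedGenes))
    stop("feature mismatch between model and pseudo-cells")
  trees <- .flatten_forest(model@forest)
  covers <- .forest_cover(trees, model@trainingData)
  res <- .forest_shap(trees, covers, x)
  phi <- res$phi
  dimnames(phi) <- list(rownames(x), colnames(x))
  list(phi = phi, base = res$base,
       pred = as.numeric(rowSums(phi) + res$base))
}

#' Rank genes by mean absolute Shapley value
#'
#' Gene importance is the mean of the absolute per-instance attributions
#' (days); ranks are assigned in decreasing importance with ties broken
#' by gene-name order.
#'
#' @param model a [ClockModel-class].
#' @param pc pseudo-cells to attribute over; defaults to the training
#'   set, matching the convention that importances are calculated from
#'   the training data.
#' @return data.frame `cell_type`, `gene`, `mean_abs_shap`, `rank`.
#' @export
shapRank <- function(model, pc = NULL) {
  sv <- shapValues(model, pc)
  imp <- colMeans(abs(sv$phi))
  ord <- order(-imp, names(imp))
  data.frame(cell_type = model@cellType,
             gene = names(imp)[ord],
             mean_abs_shap = as.numeric(imp[ord]),
             rank = seq_along(imp),
             stringsAsFactors = FALSE)
}

#' Reduce a clock to its optimal top-SHAP gene count and retrain
#'
#' Genes are ranked by mean absolute Shapley value on the training
#' pseudo-cells; for each candidate count on the ladder
#' `{5, 10, 20, 50, 100, 200, all}` (truncated to the gene count) the
#' top-k genes are scored by cross-validated MSE using the model's fixed
#' tuned hyperparameters; the smallest k achieving the minimum mean CV
#' MSE wins and the final forest is retrained on all training
#' pseudo-cells with those genes.
#'
#' @param model a tuned [ClockModel-class].
#' @param cv_folds cross-validation folds (default 5).
#' @param seed integer seed for folds and forests.
#' @param ladder candidate gene counts.
#' @return a new [ClockModel-class] restricted to the optimal genes; its
#'   provenance records the ladder and per-k CV MSE.
#' @export
selectTopGenesRetrain <- function(model, cv_folds = 5L, seed = 1L,
                                  ladder = c(5L, 10L, 20L, 50L, 100L, 200L)) {
  stopifnot(is(model, "ClockModel"), cv_folds >= 2)
  rk <- shapRank(model)
  p <- nrow(rk)
  ks <- sort(unique(c(ladder[ladder < p], p)))
  x <- model@trainingData
  y <- model@trainingAges
  hp <- as.data.frame(model@hyperParams)
  mse <- .with_seed(seed, {
    folds <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    vapply(ks, function(k) {
      genes_k <- rk$gene[seq_len(k)]
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        fit <- .fit_ranger(x[tr, genes_k, drop = FALSE], y[tr], hp,
                           seed = .derive_seed(seed, k * 10L + f))
        pred <- predict(fit, data = x[!tr, genes_k, drop = FALSE],
                        num.threads = 1L)$predictions
        mean((pred - y[!tr])^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  })
  k_best <- ks[which.min(mse)]   # which.min takes the smallest k on ties
  genes_best <- rk$gene[seq_len(k_best)]
  forest <- .fit_ranger(x[, genes_best, drop = FALSE], y, hp,
                        seed = .derive_seed(seed, 998L))
  out <- model
  out@selectedGenes <- genes_best
  out@forest <- forest
  out@trainingData <- x[, genes_best, drop = FALSE]
  out@provenance$gene_count_ladder <- data.frame(k = ks, cv_mse = mse)
  out@provenance$k_optimal <- k_best
  validObject(out)
  out
}

#' Prioritize genes across cell-type-specific clocks
#'
#' Aggregates per-model Shapley importances: genes appearing in at least
#' `min_models` models are ranked by the unweighted mean of their
#' per-model mean absolute Shapley values; genes present in every model
#' are flagged.
#'
#' @param importances named list (by cell type) of [shapRank()] tables,
#'   at least two.
#' @param min_models minimum number of involving models (default 2).
#' @return data.frame `gene`, `n_models_involving`, `aggregate_score`,
#'   `in_all_models`, sorted by decreasing score.
#' @export
crossTypePrioritize <- function(importances, min_models = 2L) {
  stopifnot(is.list(importances), length(importances) >= 2)
  all_imp <- do.call(rbind, importances)
  ag <- stats::aggregate(mean_abs_shap ~ gene, data = all_imp,
                         FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(gene = ag$gene,
                    n_models_involving = as.integer(ag$mean_abs_shap[, "n"]),
                    aggregate_score = as.numeric(ag$mean_abs_shap[, "mean"]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_models_involving >= min_models, , drop = FALSE]
  out$in_all_models <- out$n_models_involving == length(importances)
  out <- out[order(-out$aggregate_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
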