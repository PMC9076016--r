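#' Assemble an end-to-end run configuration
#'
#' Collects every tunable of the pipeline — QC thresholds, clock
#' parameters, signature file, seeds — into one serializable object.
#' A single master seed fans out into fixed per-stage seeds so each
#' stage is independently reproducible; the whole configuration is
#' echoed (with its fingerprint) into every output.
#'
#' @param input directory of a cohort written by [writeCohort()], or
#'   `NULL` when `spec` is given.
#' @param spec a [cohortSpec()] to simulate the input cohort from.
#' @param qc a [qcThresholds()].
#' @param clock a [clockConfig()].
#' @param impute_method `"none"` or `"knn_smooth"`.
#' @param signatures path to a signature YAML (`NULL` skips scoring).
#' @param run_shap compute Shapley rankings for retained models.
#' @param min_models cross-type prioritization threshold.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
runConfig <- function(input = NULL, spec = NULL, qc = qcThresholds(),
                      clock = clockConfig(), impute_method = "none",
                      signatures = NULL, run_shap = TRUE, min_models = 2L,
                      seed = 1L) {
  if (is.null(input) && is.null(spec))
    stop("provide either an input directory or a cohort spec")
  clock$seed <- .derive_seed(seed, 40L)
  cfg <- list(input = input, spec = spec, qc = qc, clock = clock,
              impute_method = impute_method, signatures = signatures,
              run_shap = isTRUE(run_shap), min_models = as.integer(min_models),
              seed = as.integer(seed))
  cfg$fingerprint <- .fingerprint(cfg[setdiff(names(cfg), "fingerprint")])
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [runConfig()] fields
#'   (`spec`, `qc` and `clock` given as parameter maps).
#' @return a `run_config`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$spec)) args$spec <- do.call(cohortSpec, y$spec)
  if (!is.null(y$qc)) args$qc <- do.call(qcThresholds, y$qc)
  if (!is.null(y$clock)) args$clock <- do.call(clockConfig, y$clock)
  for (f in c("impute_method", "signatures", "run_shap", "min_models", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(runConfig, args)
}

#' Run the full analysis pipeline
#'
#' Executes QC filtering, normalization, optional imputation and
#' signature scoring, the per-cell-type clock, and Shapley-based gene
#' prioritization, writing a summary JSON plus per-stage TSVs under
#' `out_dir`. Rerunning with an identical configuration reproduces every
#' output byte for byte.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory (created if absent); `NULL` skips
#'   writing and just returns the results.
#' @return (invisibly) list with `dataset`, `clock` (models/evaluations/
#'   summary), `scores`, `importances`, `cross_type`, `summary`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ds <- if (!is.null(config$input)) readCohort(config$input)
        else generateCohort(config$spec)$dataset
  ds <- filterCells(ds, config$qc)
  qc_rep <- qcReport(ds)
  ds <- logNormalize(ds)
  if (config$impute_method != "none")
    ds <- imputeExpression(ds, method = config$impute_method)

  scores <- NULL
  if (!is.null(config$signatures)) {
    sigs <- readSignatures(config$signatures)
    scores <- do.call(rbind, lapply(sigs, function(sg) {
      tryCatch(moduleScore(ds, sg, seed = .derive_seed(config$seed, 20L)),
               error = function(e) NULL)
    }))
  }

  subsets <- subsetCellTypes(ds, config$qc)
  clock <- runClockAllTypes(subsets, config$clock)

  importances <- NULL; cross <- NULL
  if (config$run_shap && length(clock$models)) {
    retained <- names(clock$evaluations)[vapply(clock$evaluations,
                                                function(e) isTRUE(e@retained), logical(1))]
    use <- if (length(retained) >= 2) retained else names(clock$models)
    importances <- lapply(clock$models[use], shapRank)
    if (length(importances) >= 2)
      cross <- crossTypePrioritize(importances, config$min_models)
  }

  summary <- list(
    config_fingerprint = config$fingerprint,
    seed = config$seed,
    qc = qc_rep[c("n_input", "removed_low_genes", "removed_high_genes",
                  "removed_high_mito", "n_retained")],
    excluded_cell_types = attr(subsets, "excluded"),
    skipped_cell_types = clock$skipped,
    models = clock$summary,
    retained_cell_types = if (is.null(clock$summary)) character() else
      clock$summary$cell_type[clock$summary$retained],
    per_period = lapply(clock$evaluations, function(e) e@perPeriod),
    cross_type_top = if (!is.null(cross)) head(cross, 25) else NULL)

  res <- list(dataset = ds, clock = clock, scores = scores,
              importances = importances, cross_type = cross,
              summary = summary)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, config, out_dir)
  invisible(res)
}

.write_pipeline_outputs <- function(res, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  if (!is.null(res$clock$summary))
    write.table(res$clock$summary, file.path(out_dir, "clock_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (ty in names(res$clock$evaluations)) {
    ev <- res$clock$evaluations[[ty]]
    write.table(ev@subjects,
                file.path(out_dir, paste0("predictions_", gsub("[^A-Za-z0-9]+", "_", ty), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$importances)) {
    imp <- do.call(rbind, res$importances)
    write.table(imp, file.path(out_dir, "gene_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$cross_type))
    write.table(res$cross_type, file.path(out_dir, "cross_type_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$scores))
    write.table(res$scores, file.path(out_dir, "module_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Save / load a fitted clock model bundle
#'
#' The bundle directory holds `selected_genes.tsv`, `scaler.json`,
#' `hyperparameters.json`, `provenance.json` and the serialized forest.
#'
#' @param model a [ClockModel-class].
#' @param dir bundle directory.
#' @return `saveClockModel`: invisibly the directory;
#'   `readClockModel`: the restored model.
#' @export
saveClockModel <- function(model, dir) {
  stopifnot(is(model, "ClockModel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(model@selectedGenes, file.path(dir, "selected_genes.tsv"))
  jsonlite::write_json(model@scaler, file.path(dir, "scaler.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(model@hyperParams,
                         list(lasso_penalty = model@lassoPenalty,
                              seed = model@seed)),
                       file.path(dir, "hyperparameters.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model@provenance[setdiff(names(model@provenance), "split")],
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname saveClockModel
#' @param dir bundle directory.
#' @export
readClockModel <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
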