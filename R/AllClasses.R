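## Central S4 classes. The cohort carrier extends SingleCellExperiment and is
## stored genes x cells (Bioconductor orientation); the on-disk Matrix Market
## layout written by writeCohort() is cells x genes, recorded in the file
## header.

#' CohortExperiment: single-cell cohort with pregnancy metadata
#'
#' A [SingleCellExperiment::SingleCellExperiment] whose `colData` carries the
#' per-cell metadata the gestational-age analyses require: `cell_id`,
#' `subject_id`, `cell_type`, `ga_days` (gestational age in days; 0 for
#' non-pregnant), `ga_weeks` (`floor(ga_days / 7)`), `stage` (one of
#' `"non-pregnant"`, `"first"`, `"second"`, `"third"`), plus QC columns
#' `n_genes_detected` and `mito_pct`. `metadata(x)$layer_tag` names the
#' active assay, one of `"counts"`, `"lognorm"`, `"imputed"`, `"scaled"`.
#'
#' @slot .. inherited from `SingleCellExperiment`.
#' @export
setClass("CohortExperiment", contains = "SingleCellExperiment")

.required_cols <- c("cell_id", "subject_id", "cell_type", "ga_days",
                    "ga_weeks", "stage")
.layer_tags <- c("counts", "lognorm", "imputed", "scaled")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  miss <- setdiff(.required_cols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene names must be unique")
  tag <- metadata(object)$layer_tag
  if (is.null(tag) || !tag %in% .layer_tags)
    msg <- c(msg, "metadata(x)$layer_tag must be one of counts/lognorm/imputed/scaled")
  else if (!tag %in% assayNames(object))
    msg <- c(msg, sprintf("active layer '%s' is not an assay", tag))
  if (!length(miss) && ncol(object) > 0) {
    if (!all(cd$ga_days >= 0))
      msg <- c(msg, "ga_days must be >= 0")
    if (!all(cd$ga_weeks == floor(cd$ga_days / 7)))
      msg <- c(msg, "ga_weeks must equal floor(ga_days / 7)")
    if (!all(cd$stage %in% c("non-pregnant", "first", "second", "third")))
      msg <- c(msg, "stage must be non-pregnant/first/second/third")
    else if (!all(cd$stage == stageFromWeeks(cd$ga_weeks)))
      msg <- c(msg, "stage is inconsistent with ga_weeks under the stage map")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortExperiment from counts and per-cell metadata
#'
#' @param counts genes x cells matrix of non-negative counts (coerced to
#'   sparse). Row names are gene symbols and must be unique.
#' @param cell_meta data.frame with one row per cell and at least
#'   `cell_id`, `subject_id`, `cell_type`, `ga_days`. `ga_weeks` and
#'   `stage` are derived when absent; `n_genes_detected` and `mito_pct`
#'   are always recomputed from the counts.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (case-insensitive), default `"MT-"`.
#' @return a validated [CohortExperiment-class].
#' @export
#' @examples
#' counts <- Matrix::Matrix(matrix(rpois(20, 2), nrow = 5,
#'   dimnames = list(paste0("G", 1:5), NULL)), sparse = TRUE)
#' meta <- data.frame(cell_id = paste0("c", 1:4), subject_id = "S1",
#'   cell_type = "NK", ga_days = 100)
#' CohortExperiment(counts, meta)
CohortExperiment <- function(counts, cell_meta, mito_prefix = "MT-") {
  stopifnot(is.data.frame(cell_meta) || is(cell_meta, "DataFrame"))
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cell_meta <- as.data.frame(cell_meta)
  stopifnot(ncol(counts) == nrow(cell_meta))
  if (is.null(rownames(counts)))
    stop("counts must carry gene symbols as rownames")
  cell_meta$ga_days <- as.integer(cell_meta$ga_days)
  if (is.null(cell_meta$ga_weeks))
    cell_meta$ga_weeks <- floor(cell_meta$ga_days / 7)
  cell_meta$ga_weeks <- as.integer(cell_meta$ga_weeks)
  if (is.null(cell_meta$stage))
    cell_meta$stage <- stageFromWeeks(cell_meta$ga_weeks)
  cell_meta$n_genes_detected <- .detected_genes(counts)
  cell_meta$mito_pct <- .mito_pct(counts, mito_prefix)
  cell_meta <- cell_meta[, c(.required_cols,
                             setdiff(colnames(cell_meta), .required_cols)),
                         drop = FALSE]
  colnames(counts) <- cell_meta$cell_id
  sce <- SingleCellExperiment(assays = list(counts = counts),
                              colData = DataFrame(cell_meta, row.names = cell_meta$cell_id))
  metadata(sce)$layer_tag <- "counts"
  metadata(sce)$mito_prefix <- mito_prefix
  new("CohortExperiment", sce)
}

#' @describeIn CohortExperiment subject identifier per cell.
#' @param x a `CohortExperiment`.
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @export
setMethod("subjectID", "CohortExperiment", function(x) colData(x)$subject_id)

#' @describeIn CohortExperiment annotated cell type per cell.
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))
#' @export
setMethod("cellType", "CohortExperiment", function(x) colData(x)$cell_type)

#' @describeIn CohortExperiment gestational age in days per cell.
#' @export
setGeneric("gaDays", function(x) standardGeneric("gaDays"))
#' @export
setMethod("gaDays", "CohortExperiment", function(x) colData(x)$ga_days)

#' @describeIn CohortExperiment gestational age in completed weeks.
#' @export
setGeneric("gaWeeks", function(x) standardGeneric("gaWeeks"))
#' @export
setMethod("gaWeeks", "CohortExperiment", function(x) colData(x)$ga_weeks)

#' @describeIn CohortExperiment pregnancy stage label per cell.
#' @export
setGeneric("pregnancyStage", function(x) standardGeneric("pregnancyStage"))
#' @export
setMethod("pregnancyStage", "CohortExperiment", function(x) colData(x)$stage)

#' @describeIn CohortExperiment name of the active expression layer.
#' @export
setGeneric("layerTag", function(x) standardGeneric("layerTag"))
#' @export
setMethod("layerTag", "CohortExperiment", function(x) metadata(x)$layer_tag)

#' @describeIn CohortExperiment detected (nonzero) genes per cell.
#' @export
setGeneric("detectedGenes", function(x) standardGeneric("detectedGenes"))
#' @export
setMethod("detectedGenes", "CohortExperiment", function(x) colData(x)$n_genes_detected)

#' @describeIn CohortExperiment mitochondrial count percentage per cell.
#' @export
setGeneric("mitoPercent", function(x) standardGeneric("mitoPercent"))
#' @export
setMethod("mitoPercent", "CohortExperiment", function(x) colData(x)$mito_pct)

#' @describeIn CohortExperiment QC filter report, if the object has been
#'   through [filterCells()].
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))
#' @export
setMethod("qcReport", "CohortExperiment", function(x) metadata(x)$qc_report)

## Matrix of the active layer.
.active_assay <- function(x) assay(x, layerTag(x))

setMethod("show", "CohortExperiment", function(object) {
  cat(sprintf("CohortExperiment: %d genes x %d cells\n",
              nrow(object), ncol(object)))
  cat(sprintf("  active layer: %s | subjects: %d | cell types: %d\n",
              layerTag(object), length(unique(subjectID(object))),
              length(unique(cellType(object)))))
  st <- table(pregnancyStage(object))
  cat("  stages:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
})

#' GeneSignature: a named gene set with a role
#'
#' @slot name scalar character, signature name.
#' @slot genes character vector of unique gene symbols.
#' @slot role one of `"ISG"`, `"cytotoxicity"`, `"apoptosis"`,
#'   `"exhaustion"`, `"GO_pathway"`, `"custom"`.
#' @export
setClass("GeneSignature",
         representation(name = "character", genes = "character", role = "character"))

.signature_roles <- c("ISG", "cytotoxicity", "apoptosis", "exhaustion",
                      "GO_pathway", "custom")

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty scalar")
  if (length(object@genes) == 0L)
    msg <- c(msg, "genes must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes are rejected")
  if (length(object@role) != 1L || !object@role %in% .signature_roles)
    msg <- c(msg, paste("role must be one of", paste(.signature_roles, collapse = "/")))
  if (length(msg)) msg else TRUE
})

#' Create a gene signature
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (duplicates rejected).
#' @param role signature role; default `"custom"`.
#' @return a [GeneSignature-class].
#' @export
#' @examples
#' geneSignature("exhaustion", c("LAG3", "PDCD1", "CTLA4", "HAVCR2", "TOX"),
#'               role = "exhaustion")
geneSignature <- function(name, genes, role = "custom") {
  new("GeneSignature", name = name, genes = as.character(genes), role = role)
}

#' @describeIn geneSignature gene symbols of a signature.
#' @param x a `GeneSignature`.
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes\n", object@name,
              object@role, length(object@genes)))
})

#' PseudoCellSet: median-aggregated pseudo-cell profiles
#'
#' Each row of `exprs` is the per-gene median over a fixed-size group of
#' same-subject cells; `meta` records `subject_id`, `ga_days`,
#' `cell_type` and `group_index` for every pseudo-cell.
#'
#' @slot exprs numeric matrix, pseudo-cells x genes.
#' @slot meta data.frame with one row per pseudo-cell.
#' @slot groupSize integer, cells aggregated per pseudo-cell.
#' @slot layerTag character, the layer the medians were taken on
#'   (`"lognorm"`, `"imputed"` or `"scaled"`).
#' @export
setClass("PseudoCellSet",
         representation(exprs = "matrix", meta = "data.frame",
                        groupSize = "integer", layerTag = "character"))

setValidity("PseudoCellSet", function(object) {
  msg <- character()
  if (nrow(object@exprs) != nrow(object@meta))
    msg <- c(msg, "exprs rows and meta rows differ")
  need <- c("subject_id", "ga_days", "cell_type", "group_index")
  miss <- setdiff(need, colnames(object@meta))
  if (length(miss))
    msg <- c(msg, paste("meta lacks", paste(miss, collapse = ", ")))
  if (is.null(colnames(object@exprs)))
    msg <- c(msg, "exprs must carry gene names as colnames")
  if (length(msg)) msg else TRUE
})

#' @describeIn PseudoCellSet pseudo-cell expression matrix (pseudo-cells x genes).
#' @param x a `PseudoCellSet`.
#' @export
setGeneric("pcExprs", function(x) standardGeneric("pcExprs"))
#' @export
setMethod("pcExprs", "PseudoCellSet", function(x) x@exprs)

#' @describeIn PseudoCellSet pseudo-cell metadata.
#' @export
setGeneric("pcMeta", function(x) standardGeneric("pcMeta"))
#' @export
setMethod("pcMeta", "PseudoCellSet", function(x) x@meta)

setMethod("show", "PseudoCellSet", function(object) {
  cat(sprintf("PseudoCellSet: %d pseudo-cells x %d genes (group size %d, layer %s)\n",
              nrow(object@exprs), ncol(object@exprs), object@groupSize,
              object@layerTag))
  cat(sprintf("  subjects: %d\n", length(unique(object@meta$subject_id))))
})

#' SplitPlan: subject-level train/test assignment
#'
#' @slot trainSubjects,testSubjects disjoint subject id vectors whose union
#'   covers all pregnant subjects of the dataset split.
#' @slot ratio numeric train fraction.
#' @slot strata data.frame mapping subject to period stratum and side.
#' @slot seed integer seed used for the shuffle.
#' @export
setClass("SplitPlan",
         representation(trainSubjects = "character", testSubjects = "character",
                        ratio = "numeric", strata = "data.frame", seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainSubjects, object@testSubjects)))
    "train and test subjects overlap" else TRUE
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test subjects (ratio %.2f, seed %d)\n",
              length(object@trainSubjects), length(object@testSubjects),
              object@ratio, object@seed))
})

#' ClockModel: fitted cell-type-specific gestational-age predictor
#'
#' @slot cellType cell type the model was trained on.
#' @slot selectedGenes ordered gene list (by decreasing |LASSO coefficient|,
#'   or by SHAP rank after [selectTopGenesRetrain()]).
#' @slot scaler per-gene centering/scaling parameters fitted on training
#'   pseudo-cells (list with `center`, `scale`, `genes`).
#' @slot lassoPenalty LASSO penalty used for gene selection.
#' @slot forest fitted `ranger` regression forest.
#' @slot hyperParams list of tuned hyperparameters.
#' @slot cvSummary data.frame of per-candidate CV RMSE.
#' @slot trainingData scaled training matrix (pseudo-cells x selected genes),
#'   retained as the background distribution for Shapley attribution.
#' @slot trainingAges gestational ages (days) of the training pseudo-cells.
#' @slot seed integer seed of the tuning run.
#' @slot provenance list of fingerprints and parameters.
#' @export
setClass("ClockModel",
         representation(cellType = "character", selectedGenes = "character",
                        scaler = "list", lassoPenalty = "numeric",
                        forest = "ANY", hyperParams = "list",
                        cvSummary = "data.frame", trainingData = "matrix",
                        trainingAges = "numeric", seed = "integer",
                        provenance = "list"))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!all(object@selectedGenes %in% colnames(object@trainingData)))
    msg <- c(msg, "selectedGenes must be columns of trainingData")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClockModel genes the regressor uses, in rank order.
#' @param x a `ClockModel`.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))
#' @export
setMethod("selectedGenes", "ClockModel", function(x) x@selectedGenes)

setMethod("show", "ClockModel", function(object) {
  cat(sprintf("ClockModel [%s]: %d genes, %d training pseudo-cells\n",
              object@cellType, length(object@selectedGenes),
              nrow(object@trainingData)))
  hp <- object@hyperParams
  cat(sprintf("  forest: %d trees, max depth %s, min leaf %d, mtry %d\n",
              hp$num_trees, ifelse(hp$max_depth == 0, "unlimited", hp$max_depth),
              hp$min_node_size, hp$mtry))
})

#' ClockEvaluation: subject-level test performance of a clock
#'
#' @slot subjects data.frame with `subject_id`, `ga_true_days`,
#'   `ga_pred_days`, `period`.
#' @slot R Pearson correlation between predicted and true age over subjects.
#' @slot p two-sided p-value of the correlation test.
#' @slot rmse root mean squared error in days.
#' @slot retained logical: `R >= retention threshold` (default 0.8).
#' @slot perPeriod data.frame of per-period (early/middle/late) metrics.
#' @export
setClass("ClockEvaluation",
         representation(subjects = "data.frame", R = "numeric", p = "numeric",
                        rmse = "numeric", retained = "logical",
                        perPeriod = "data.frame"))

setMethod("show", "ClockEvaluation", function(object) {
  cat(sprintf("ClockEvaluation: %d test subjects | R = %.3f (p = %.3g), RMSE = %.2f days%s\n",
              nrow(object@subjects), object@R, object@p, object@rmse,
              if (isTRUE(object@retained)) " [retained]" else ""))
})

#' CohortTruth: ground truth of a synthetic cohort
#'
#' @slot ageGenes gene symbols carrying a planted gestational-age effect.
#' @slot slopes named numeric, log2 change per day for every gene (zero for
#'   non-planted genes).
#' @slot subjectAges named numeric, gestational age in days per subject
#'   (0 for non-pregnant).
#' @slot baseMeans genes x cell-type matrix of negative-binomial baseline
#'   means (before subject and age effects).
#' @slot ageGenesByType list mapping cell type to its planted genes when
#'   disjoint per-type sets were requested.
#' @export
setClass("CohortTruth",
         representation(ageGenes = "character", slopes = "numeric",
                        subjectAges = "numeric", baseMeans = "matrix",
                        ageGenesByType = "list"))

setValidity("CohortTruth", function(object) {
  msg <- character()
  if (!all(object@ageGenes %in% names(object@slopes)))
    msg <- c(msg, "ageGenes must appear in slopes")
  nz <- names(object@slopes)[object@slopes != 0]
  if (!all(nz %in% object@ageGenes))
    msg <- c(msg, "slopes must be zero for all non-planted genes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf("CohortTruth: %d planted age genes, %d subjects\n",
              length(object@ageGenes), length(object@subjectAges)))
})
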