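#' QC thresholds for cell filtering and cell-type retention
#'
#' Defaults follow the standard single-cell PBMC filters used upstream of
#' the clock: cells with fewer than 800 or more than 6000 detected genes
#' are discarded (bounds themselves survive), cells with more than 5%
#' mitochondrial counts are discarded (5.0% survives), and annotated cell
#' types with fewer than 1000 cells are excluded from model building.
#'
#' @param min_genes,max_genes inclusive bounds on detected (nonzero)
#'   genes per cell.
#' @param max_mito_pct inclusive upper bound on mitochondrial count
#'   percentage.
#' @param min_cells_per_type minimum cells for a cell type to be retained
#'   by [subsetCellTypes()].
#' @return a list of class `qc_thresholds`.
#' @export
qcThresholds <- function(min_genes = 800L, max_genes = 6000L,
                         max_mito_pct = 5, min_cells_per_type = 1000L) {
  stopifnot(min_genes > 0, max_genes > min_genes, max_mito_pct > 0,
            min_cells_per_type > 0)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_pct = max_mito_pct,
                 min_cells_per_type = as.integer(min_cells_per_type)),
            class = "qc_thresholds")
}

#' Filter cells on detected genes and mitochondrial percentage
#'
#' Retains cells whose detected-gene count lies in
#' `[min_genes, max_genes]` and whose mitochondrial percentage is at most
#' `max_mito_pct`. A report of removals per rule is stored in
#' `metadata(x)$qc_report` (see [qcReport()]).
#'
#' @param ds a [CohortExperiment-class] with active layer `"counts"`.
#' @param thresholds a [qcThresholds()].
#' @return the filtered `CohortExperiment`.
#' @export
filterCells <- function(ds, thresholds = qcThresholds()) {
  stopifnot(is(ds, "CohortExperiment"))
  if (layerTag(ds) != "counts")
    stop("filterCells requires the counts layer (got '", layerTag(ds), "')")
  det <- detectedGenes(ds)
  mito <- mitoPercent(ds)
  low <- det < thresholds$min_genes
  high <- det > thresholds$max_genes
  mt <- mito > thresholds$max_mito_pct
  keep <- !(low | high | mt)
  out <- ds[, keep]
  metadata(out)$qc_report <- list(
    n_input = ncol(ds),
    removed_low_genes = sum(low),
    removed_high_genes = sum(high),
    removed_high_mito = sum(mt),
    n_retained = sum(keep),
    thresholds = unclass(thresholds)[1:3])
  out
}

#' Log-normalize counts
#'
#' Divides each cell's counts by its total, multiplies by `scale_factor`
#' and applies `log1p`. Cells with zero total counts are set to all zeros
#' with a warning. The result is stored as the `"lognorm"` assay and
#' becomes the active layer.
#'
#' @param ds a [CohortExperiment-class] with a counts layer.
#' @param scale_factor positive scale, default `1e4`.
#' @return the `CohortExperiment` with a `lognorm` layer.
#' @export
logNormalize <- function(ds, scale_factor = 1e4) {
  stopifnot(is(ds, "CohortExperiment"), scale_factor > 0)
  counts <- assay(ds, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0) && ncol(ds) > 0)
    warning(sum(tot == 0), " cell(s) with zero total counts set to all-zero")
  fac <- ifelse(tot > 0, scale_factor / tot, 0)
  norm <- counts %*% Matrix::Diagonal(x = fac)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  assay(ds, "lognorm") <- norm
  metadata(ds)$layer_tag <- "lognorm"
  ds
}

#' Split a cohort into per-cell-type datasets
#'
#' Returns one dataset per cell type with at least `min_cells_per_type`
#' cells ("fewer than 1000" read strictly: a type with exactly 1000 cells
#' is retained). Excluded types are listed in the `"excluded"` attribute.
#'
#' @param ds a [CohortExperiment-class].
#' @param thresholds a [qcThresholds()].
#' @return named list of `CohortExperiment`, one per retained type.
#' @export
subsetCellTypes <- function(ds, thresholds = qcThresholds()) {
  stopifnot(is(ds, "CohortExperiment"))
  tab <- table(cellType(ds))
  keep <- names(tab)[tab >= thresholds$min_cells_per_type]
  out <- lapply(setNames(keep, keep), function(ty) ds[, cellType(ds) == ty])
  attr(out, "excluded") <- setdiff(names(tab), keep)
  out
}

#' Impute (smooth) expression
#'
#' Pluggable zero-imputation hook applied between normalization and
#' scaling. `method = "none"` is the identity. `method = "knn_smooth"`
#' replaces each cell by the mean of its `k` nearest neighbours
#' (including itself) in a `n_pcs`-dimensional PCA of the log-normalized
#' layer — a simple diffusion-style smoother standing behind the same
#' interface a heavier imputation algorithm would use.
#'
#' @param ds a [CohortExperiment-class] with active layer `"lognorm"`.
#' @param method `"none"` or `"knn_smooth"`.
#' @param k neighbours per cell (including self); must be `< ncol(ds)`.
#' @param n_pcs principal components used for the neighbour search.
#' @return the `CohortExperiment`; for `knn_smooth` with an added
#'   `"imputed"` active layer, unchanged for `"none"`.
#' @export
imputeExpression <- function(ds, method = c("none", "knn_smooth"),
                             k = 15L, n_pcs = 20L) {
  method <- match.arg(method)
  stopifnot(is(ds, "CohortExperiment"))
  if (method == "none") return(ds)
  if (layerTag(ds) != "lognorm")
    stop("imputeExpression requires the lognorm layer")
  n <- ncol(ds)
  if (k >= n) stop("k must be smaller than the number of cells")
  x <- as.matrix(Matrix::t(assay(ds, "lognorm")))    # cells x genes
  npc <- min(n_pcs, n - 1L, ncol(x))
  ## PCA via the gene-gene covariance: cheaper than a full SVD when
  ## cells far outnumber the requested components
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / max(1, n - 1), symmetric = TRUE)
  pcs <- xc %*% ev$vectors[, seq_len(npc), drop = FALSE]
  sm <- matrix(0, nrow = n, ncol = ncol(x))
  block <- 512L
  sq <- rowSums(pcs^2)                    # ||a-b||^2 = |a|^2 + |b|^2 - 2ab
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(pcs[idx, , drop = FALSE], pcs)
    for (j in seq_along(idx)) {
      nn <- order(d2[j, ])[seq_len(k)]
      sm[idx[j], ] <- colMeans(x[nn, , drop = FALSE])
    }
  }
  imp <- t(sm)                 # dense: smoothed values have few zeros
  dimnames(imp) <- dimnames(assay(ds, "lognorm"))
  assay(ds, "imputed") <- imp
  metadata(ds)$layer_tag <- "imputed"
  ds
}

#' Center and scale genes to zero mean and unit variance
#'
#' Fits per-gene mean and sample standard deviation on the supplied data
#' and returns both the transformed data and the scaler so test data can
#' be transformed with training parameters. Zero-variance genes map to
#' all-zero columns and their sd is recorded as 1, which makes the stored
#' transform invertible everywhere.
#'
#' @param x a [CohortExperiment-class] (active layer `lognorm`/`imputed`)
#'   or a [PseudoCellSet-class].
#' @return list with `data` (same class as `x`, scaled) and `scaler`
#'   (list `center`, `scale`, `genes`).
#' @export
setGeneric("scaleGenes", function(x) standardGeneric("scaleGenes"))

#' @rdname scaleGenes
#' @export
setMethod("scaleGenes", "CohortExperiment", function(x) {
  if (!layerTag(x) %in% c("lognorm", "imputed"))
    stop("scaleGenes requires a lognorm or imputed layer")
  m <- as.matrix(.active_assay(x))              # genes x cells
  ctr <- rowMeans(m)
  sds <- apply(m, 1, sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  scaled <- (m - ctr) / sds
  assay(x, "scaled") <- scaled
  metadata(x)$layer_tag <- "scaled"
  list(data = x, scaler = list(center = ctr, scale = sds, genes = rownames(m)))
})

#' @rdname scaleGenes
#' @export
setMethod("scaleGenes", "PseudoCellSet", function(x) {
  m <- x@exprs                                   # pseudo-cells x genes
  ctr <- colMeans(m)
  sds <- matrixStats::colSds(m)
  sds[!is.finite(sds) | sds == 0] <- 1
  x@exprs <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  x@layerTag <- "scaled"
  list(data = x,
       scaler = list(center = ctr, scale = sds, genes = colnames(m)))
})

#' Apply (or invert) a stored gene scaler
#'
#' @param x a [PseudoCellSet-class] or plain pseudo-cells x genes matrix.
#' @param scaler the `scaler` element returned by [scaleGenes()].
#' @param inverse if `TRUE`, undo the transform.
#' @return object of the same kind as `x`, transformed.
#' @export
applyScaler <- function(x, scaler, inverse = FALSE) {
  m <- if (is(x, "PseudoCellSet")) x@exprs else as.matrix(x)
  g <- intersect(colnames(m), scaler$genes)
  if (!length(g)) stop("scaler genes do not match data")
  m <- m[, scaler$genes[scaler$genes %in% colnames(m)], drop = FALSE]
  ctr <- scaler$center[colnames(m)]
  sds <- scaler$scale[colnames(m)]
  out <- if (inverse) sweep(sweep(m, 2, sds, "*"), 2, ctr, "+")
         else sweep(sweep(m, 2, ctr), 2, sds, "/")
  if (is(x, "PseudoCellSet")) {
    x@exprs <- out
    x@layerTag <- if (inverse) "lognorm" else "scaled"
    x
  } else out
}
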