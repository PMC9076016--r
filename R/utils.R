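#' Map gestational weeks to pregnancy stage
#'
#' Stage labels follow the clinical trimester convention: `"non-pregnant"`
#' for gestational age 0, `"first"` for weeks 1-13, `"second"` for weeks
#' 14-27 and `"third"` for week 28 onwards. An optional finer map splits
#' the first trimester into an early (weeks 6-9) and late (weeks 10-13)
#' phase, mirroring the interferon-response substaging used for monocytes.
#'
#' @param weeks integer vector of gestational weeks (0 = non-pregnant).
#' @param substage_early logical; if `TRUE` return
#'   `"first-early"`/`"first-late"` instead of `"first"`.
#' @return character vector of stage labels.
#' @export
#' @examples
#' stageFromWeeks(c(0, 6, 13, 14, 27, 28, 40))
stageFromWeeks <- function(weeks, substage_early = FALSE) {
  stopifnot(is.numeric(weeks), all(weeks >= 0))
  out <- character(length(weeks))
  out[weeks == 0] <- "non-pregnant"
  first <- weeks >= 1 & weeks <= 13
  if (substage_early) {
    out[first & weeks <= 9] <- "first-early"
    out[first & weeks > 9] <- "first-late"
  } else {
    out[first] <- "first"
  }
  out[weeks >= 14 & weeks <= 27] <- "second"
  out[weeks >= 28] <- "third"
  out
}

#' Map gestational weeks to pregnancy period
#'
#' Periods are the strata used by the clock: `"early"` (weeks <= 13),
#' `"middle"` (weeks 14-27) and `"late"` (weeks >= 28). Non-pregnant
#' subjects (week 0) get `NA`: they take no part in clock training or
#' evaluation.
#'
#' @param weeks integer vector of gestational weeks.
#' @return character vector of `"early"`, `"middle"`, `"late"` or `NA`.
#' @export
periodFromWeeks <- function(weeks) {
  out <- rep(NA_character_, length(weeks))
  out[weeks >= 1 & weeks <= 13] <- "early"
  out[weeks >= 14 & weeks <= 27] <- "middle"
  out[weeks >= 28] <- "late"
  out
}

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is left untouched.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic fan-out of one user seed into per-stage seeds (kept < 2^31).
.derive_seed <- function(seed, stage_offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage_offset)
}

## Stable polynomial hash of an R object, hex string; used to stamp
## provenance/config fingerprints without a hashing dependency.
.fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

## Detected (nonzero) genes per cell, the Seurat nFeature reading of
## "gene expression" in the QC thresholds.
.detected_genes <- function(counts) {
  as.integer(Matrix::colSums(counts > 0))
}

## Percent of counts from mitochondrial genes (symbol prefix, case-insensitive).
.mito_pct <- function(counts, mito_prefix = "MT-") {
  is_mt <- startsWith(toupper(rownames(counts)), toupper(mito_prefix))
  tot <- Matrix::colSums(counts)
  mito <- if (any(is_mt)) Matrix::colSums(counts[is_mt, , drop = FALSE]) else 0
  pct <- ifelse(tot > 0, 100 * mito / tot, 0)
  as.numeric(pct)
}

.stars <- function(p) {
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 1e-2, "**",
        ifelse(p < 0.05, "*", "ns"))))
}
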