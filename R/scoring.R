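#' Read gene signatures from a YAML config
#'
#' The file maps signature names to a `role` and a `genes` list; the
#' package ships a starting config (cytotoxicity, apoptosis, exhaustion
#' markers and an editable interferon-stimulated-gene list) at
#' `system.file("extdata", "signatures.yaml", package = "gestclock")`.
#'
#' @param path YAML file; defaults to the bundled config.
#' @return named list of [GeneSignature-class] objects.
#' @export
readSignatures <- function(path = system.file("extdata", "signatures.yaml",
                                              package = "gestclock")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    geneSignature(nm, cfg[[nm]]$genes, role = cfg[[nm]]$role %||% "custom")
  })
  setNames(out, names(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Control-binned gene-set module score
#'
#' Per-cell gene-set activity scored against expression-matched controls:
#' genes are ranked by dataset-wide average expression and cut into
#' `n_bins` equal-frequency bins; for each signature gene, `n_ctrl`
#' control genes are drawn from its bin (without replacement within a
#' draw; the union over signature genes may repeat and is deduplicated).
#' The score is the mean expression of the matched signature genes minus
#' the mean expression of the control set. Ties at bin boundaries are
#' broken by stable gene order after ranking; the seed governs control
#' sampling only.
#'
#' @param ds a [CohortExperiment-class] with a `lognorm` (or `imputed`)
#'   active layer.
#' @param sig a [GeneSignature-class]; unmatched genes are dropped with a
#'   warning, no matched gene is an error.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return data.frame (`cell_id`, `signature`, `score`, `stage`,
#'   `cell_type`, `subject_id`), one row per cell.
#' @export
moduleScore <- function(ds, sig, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  stopifnot(is(ds, "CohortExperiment"), is(sig, "GeneSignature"))
  if (layerTag(ds) == "counts")
    stop("moduleScore expects normalized expression; run logNormalize() first")
  m <- .active_assay(ds)
  genes <- rownames(m)
  if (length(genes) < n_bins)
    stop("need at least n_bins genes")
  matched <- intersect(sig@genes, genes)
  if (!length(matched))
    stop("no signature gene matched the dataset")
  if (length(matched) < length(sig@genes))
    warning(sprintf("%d signature gene(s) not found and dropped",
                    length(sig@genes) - length(matched)))
  avg <- Matrix::rowMeans(m)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / length(genes))
  ## pools ordered by expression rank so the draw does not depend on the
  ## storage order of genes
  g_by_rank <- genes[order(rk)]
  bin_by_rank <- bin[order(rk)]
  ctrl <- .with_seed(seed, {
    unlist(lapply(matched, function(g) {
      pool <- g_by_rank[bin_by_rank == bin[match(g, genes)]]
      pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
    }))
  })
  ctrl <- unique(ctrl)
  sig_mean <- Matrix::colSums(m[matched, , drop = FALSE]) / length(matched)
  ctrl_mean <- Matrix::colSums(m[ctrl, , drop = FALSE]) / length(ctrl)
  data.frame(cell_id = colnames(ds),
             signature = sig@name,
             score = as.numeric(sig_mean - ctrl_mean),
             stage = pregnancyStage(ds),
             cell_type = cellType(ds),
             subject_id = subjectID(ds),
             stringsAsFactors = FALSE)
}

## Two-sided Wilcoxon rank-sum with the conventional switch: exact for small
## tie-free samples, normal approximation with tie correction otherwise.
## Degenerate all-equal data gives p = 1 rather than NaN.
.ranksum <- function(x, y) {
  if (length(unique(c(x, y))) == 1L)
    return(list(W = length(x) * length(y) / 2, p = 1))
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(W = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Stage-wise comparison of module scores
#'
#' Two-sided Wilcoxon rank-sum tests between pregnancy stages, with the
#' conventional significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001, otherwise `ns`). By default the
#' unit of comparison is the cell; `unit = "subject"` first averages
#' scores within subject.
#'
#' @param scores a score table from [moduleScore()] (columns `score`,
#'   `stage`, and `subject_id` when `unit = "subject"`).
#' @param pairs list of length-2 character vectors of stage labels;
#'   default all pairs present in the data.
#' @param unit `"cell"` or `"subject"`.
#' @return data.frame with `group1`, `group2`, `W`, `p`, `stars`.
#' @export
stageCompare <- function(scores, pairs = NULL, unit = c("cell", "subject")) {
  unit <- match.arg(unit)
  stopifnot(all(c("score", "stage") %in% colnames(scores)))
  if (unit == "subject") {
    agg <- stats::aggregate(score ~ subject_id + stage, data = scores, FUN = mean)
    scores <- agg
  }
  lv <- intersect(c("non-pregnant", "first", "second", "third"),
                  unique(scores$stage))
  if (is.null(pairs))
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    g1 <- scores$score[scores$stage == pr[1]]
    g2 <- scores$score[scores$stage == pr[2]]
    if (!length(g1) || !length(g2))
      stop("empty group in pair ", paste(pr, collapse = " vs "))
    ht <- .ranksum(g1, g2)
    data.frame(group1 = pr[1], group2 = pr[2], W = ht$W, p = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- .stars(out$p)
  out
}

#' Pearson correlation of gene expression with gestational week
#'
#' For each gene, the per-gestational-week mean expression (over pregnant
#' cells) is correlated with the week number using Pearson's
#' product-moment correlation and a two-sided t-test. Aggregating to
#' weekly means keeps the sample size at the number of observed weeks
#' rather than the number of cells.
#'
#' @param ds a [CohortExperiment-class], normalized layer active.
#' @param genes gene symbols to test.
#' @return data.frame `gene`, `r`, `p`, `n_weeks`, `note` (`NA` r with a
#'   zero-variance note where the correlation is undefined).
#' @export
geneAgeCorrelation <- function(ds, genes) {
  stopifnot(is(ds, "CohortExperiment"))
  genes <- intersect(genes, rownames(ds))
  if (!length(genes)) stop("no requested gene found in the dataset")
  preg <- pregnancyStage(ds) != "non-pregnant"
  wk <- gaWeeks(ds)[preg]
  uw <- sort(unique(wk))
  if (length(uw) < 3) stop("need at least 3 distinct gestational weeks")
  m <- .active_assay(ds)[genes, preg, drop = FALSE]
  grp <- factor(wk, levels = uw)
  ## weekly mean expression per gene
  agg <- sapply(levels(grp), function(l)
    Matrix::rowMeans(m[, grp == l, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1, dimnames = list(genes, levels(grp)))
  rows <- lapply(genes, function(g) {
    y <- agg[g, ]
    if (sd(y) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        n_weeks = length(uw), note = "zero variance",
                        stringsAsFactors = FALSE))
    ht <- cor.test(uw, y, method = "pearson")
    data.frame(gene = g, r = unname(ht$estimate), p = ht$p.value,
               n_weeks = length(uw), note = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum tests on normalized expression,
#' with `log2FC = log2((mean(expm1(g1)) + 1) / (mean(expm1(g2)) + 1))`
#' and Benjamini-Hochberg adjustment across tested genes. The
#' significant set applies `|log2FC| >= min_abs_log2fc` and
#' `p_adj < alpha`. Marker mode reproduces the usual cluster-marker
#' variant: genes expressed in at least `min_pct` of cells of either
#' group, positive direction only, log2FC threshold 0.25.
#'
#' @param ds a [CohortExperiment-class], normalized layer active.
#' @param cells1,cells2 cell ids (or logical/integer column indices) of
#'   the two groups; both must be non-empty.
#' @param min_abs_log2fc significance threshold on |log2FC|
#'   (default 0.3).
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param marker_mode logical; apply the marker-identification variant.
#' @param min_pct marker-mode expression fraction cutoff (default 0.25).
#' @return data.frame `gene`, `log2fc`, `p`, `p_adj`, `direction`,
#'   `pct_group1`, `pct_group2`, `significant`.
#' @export
differentialExpression <- function(ds, cells1, cells2,
                                   min_abs_log2fc = 0.3, alpha = 0.05,
                                   marker_mode = FALSE, min_pct = 0.25) {
  stopifnot(is(ds, "CohortExperiment"))
  m <- .active_assay(ds)
  resolve <- function(sel) {
    if (is.character(sel)) match(sel, colnames(m))
    else if (is.logical(sel)) which(sel)
    else as.integer(sel)
  }
  i1 <- resolve(cells1)
  i2 <- resolve(cells2)
  if (!length(i1) || !length(i2) || anyNA(i1) || anyNA(i2))
    stop("both groups must be non-empty and resolvable")
  m1 <- as.matrix(m[, i1, drop = FALSE])
  m2 <- as.matrix(m[, i2, drop = FALSE])
  pct1 <- rowMeans(m1 > 0)
  pct2 <- rowMeans(m2 > 0)
  genes <- rownames(m)
  test_idx <- seq_along(genes)
  lfc_thr <- min_abs_log2fc
  if (marker_mode) {
    test_idx <- which(pmax(pct1, pct2) >= min_pct)
    lfc_thr <- 0.25
  }
  lfc <- log2((rowMeans(expm1(m1)) + 1) / (rowMeans(expm1(m2)) + 1))
  p <- rep(NA_real_, length(genes))
  for (i in test_idx)
    p[i] <- .ranksum(m1[i, ], m2[i, ])$p
  p_adj <- rep(NA_real_, length(genes))
  p_adj[test_idx] <- p.adjust(p[test_idx], method = "BH")
  out <- data.frame(gene = genes, log2fc = as.numeric(lfc), p = p,
                    p_adj = p_adj,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    pct_group1 = as.numeric(pct1),
                    pct_group2 = as.numeric(pct2),
                    stringsAsFactors = FALSE)
  out <- out[test_idx, , drop = FALSE]
  sig <- abs(out$log2fc) >= lfc_thr & out$p_adj < alpha
  if (marker_mode) sig <- sig & out$log2fc > 0
  out$significant <- sig
  rownames(out) <- NULL
  out
}
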