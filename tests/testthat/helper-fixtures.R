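## Fixtures are built in code; nothing is read from disk except the
## package's own signature config.

## CohortExperiment from a dense genes x cells matrix of counts.
toy_cohort <- function(mat, subject = NULL, cell_type = "T", ga_days = NULL,
                       gene_names = NULL) {
  n <- ncol(mat)
  if (is.null(gene_names))
    gene_names <- sprintf("G%03d", seq_len(nrow(mat)))
  rownames(mat) <- gene_names
  meta <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    subject_id = if (is.null(subject)) rep("S1", n) else subject,
    cell_type = rep_len(cell_type, n),
    ga_days = if (is.null(ga_days)) rep(100L, n) else as.integer(ga_days),
    stringsAsFactors = FALSE)
  CohortExperiment(Matrix::Matrix(mat, sparse = TRUE), meta)
}

## Same, but with the matrix installed directly as a lognorm layer
## (values interpreted as already-normalized expression).
toy_lognorm <- function(mat, ...) {
  ds <- toy_cohort(ceiling(pmax(mat, 0)), ...)  # placeholder counts layer
  m <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(m) <- dimnames(SummarizedExperiment::assay(ds, "counts"))
  SummarizedExperiment::assay(ds, "lognorm") <- m
  S4Vectors::metadata(ds)$layer_tag <- "lognorm"
  ds
}

## PseudoCellSet built directly from a pseudo-cells x genes matrix.
make_pc <- function(x, ga_days, subject = NULL, layer = "scaled") {
  if (is.null(colnames(x))) colnames(x) <- sprintf("G%03d", seq_len(ncol(x)))
  meta <- data.frame(
    subject_id = if (is.null(subject)) sprintf("S%03d", seq_len(nrow(x))) else subject,
    ga_days = as.integer(ga_days),
    cell_type = "T",
    group_index = seq_len(nrow(x)),
    stringsAsFactors = FALSE)
  new("PseudoCellSet", exprs = x, meta = meta, groupSize = 1L,
      layerTag = layer)
}

## Small trained clock on a planted linear signal; used by several
## interpretation tests.
fit_toy_clock <- function(n = 200, p = 30, informative = 1, noise_sd = 0.5,
                          n_candidates = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("G%03d", 1:p)))
  y <- round(150 + 25 * rowSums(x[, seq_len(informative), drop = FALSE]) +
               rnorm(n, 0, noise_sd))
  pc <- make_pc(x, y)
  tuneAndTrain(pc, colnames(x), n_candidates = n_candidates, cv_folds = 3,
               seed = seed)
}

## Cover-walk expected value of one flattened tree with coalition S fixed
## to x; reference implementation for the Shapley oracle.
tree_expected_value <- function(m, cov, x, S, node = 1) {
  feat <- m[node, 3]
  if (feat < 0) return(m[node, 5])
  l <- m[node, 1] + 1; r <- m[node, 2] + 1; f <- feat + 1
  if (f %in% S) {
    if (x[f] <= m[node, 4]) tree_expected_value(m, cov, x, S, l)
    else tree_expected_value(m, cov, x, S, r)
  } else {
    (cov[l] * tree_expected_value(m, cov, x, S, l) +
       cov[r] * tree_expected_value(m, cov, x, S, r)) / cov[node]
  }
}

## Brute-force Shapley values of the cover-walk game by subset
## enumeration (exponential in p; small p only).
shapley_brute_force <- function(trees, covers, x) {
  p <- length(x)
  v <- function(S) mean(vapply(seq_along(trees), function(t)
    tree_expected_value(trees[[t]], covers[[t]], x, S), numeric(1)))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0))
                 else utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets)
        phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  phi
}
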