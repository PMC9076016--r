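---
title: "Methods: cell-type-specific transcriptomic clocks of gestational age"
author: "gestclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific transcriptomic clocks of gestational age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Pregnancy remodels the maternal peripheral immune system in a gradual,
largely monotone way: interferon-stimulated genes (ISGs) rise in NK cells
and T cells as gestation progresses, T- and B-cell activation programs
are damped, and these shifts are visible in ordinary peripheral blood
mononuclear cell (PBMC) samples. `gestclock` implements the analysis
stack needed to (i) quantify such gene-program shifts per cell and per
pregnancy stage and (ii) exploit them as a *transcriptomic clock*: a
regression model that predicts gestational age, in days, from the
single-cell expression profile of one annotated cell type.

The package is organized around an S4 carrier, `CohortExperiment`
(a `SingleCellExperiment` whose `colData` carries subject, cell type,
gestational age in days and weeks, and a derived pregnancy stage), and a
pipeline of operations that mirror a typical single-cell clock study:

1. **Synthetic cohorts** (`cohortSpec()`, `generateCohort()`) — a
   negative-binomial simulator with planted age-dependent genes, used as
   ground truth for every downstream test.
2. **QC and preprocessing** (`filterCells()`, `logNormalize()`,
   `subsetCellTypes()`, `imputeExpression()`, `scaleGenes()`).
3. **Signature scoring** (`moduleScore()`, `stageCompare()`,
   `geneAgeCorrelation()`, `differentialExpression()`).
4. **The clock** (`makePseudoCells()`, `splitSubjects()`,
   `selectGenesLasso()`, `tuneAndTrain()`, `predictSubjects()`,
   `runClockAllTypes()`).
5. **Interpretation** (`shapValues()`, `shapRank()`,
   `selectTopGenesRetrain()`, `crossTypePrioritize()`).
6. **Orchestration** (`runConfig()`, `runPipeline()`).

# The synthetic cohort generator

The generator is first-class, tested code: it defines the statistical
conditions under which every recovery property of the package is
demonstrated.

Counts for gene $g$ in a cell of type $t$ from subject $i$ are drawn

$$ y \sim \mathrm{NB}(\mu_{gti},\ \theta), \qquad
   \mu_{gti} = \lambda_g\, m_{gt}\, e^{u_i}\, 2^{\,s_g (a_i - a_{\min})} $$

with $\lambda_g$ a log-normal per-gene baseline, $m_{gt}$ a log-normal
cell-type effect, $u_i \sim N(0, \sigma_s^2)$ a subject-level random
effect shared by all genes, and $s_g$ a log2-per-day slope that is zero
except for the planted age genes, where it is scaled so expression
changes by `age_effect_log2fc` log2 units across the gestational range
(the simplest monotone model of the ISG-like behaviour the clock
exploits). Independent Bernoulli dropout zeroes each count with
probability `dropout_rate`. A designated subset of genes is named with
the `MT-` prefix and its means are calibrated so the expected
mitochondrial count fraction matches `mito_frac_mean`, which makes the
QC filter exercisable on realistic input.

Default parameters emulate the cohort structure the package targets:
136 subjects (a small non-pregnant control group included), gestational
ages 42–280 days, several cell types of very unequal abundance,
dispersion 2, dropout 0.3, subject effect 0.15 on the natural-log scale,
and 1000 genes of which 50 respond to age. Where a study condition is
not dictated by the emulated design (e.g. `baseline_log_mu = log(0.5)`,
`type_effect_sd = 0.5`), the value was chosen once as a realistic PBMC
magnitude and is not tuned thereafter.

What the generator does **not** emulate: doublets, ambient RNA,
chemistry batch effects, and the exact 18-type composition of a real
PBMC atlas. Passing recovery tests on this simulator therefore shows
that the pipeline's statistics behave as designed under its stated noise
model — not that a real cohort will reach any particular accuracy.

## A noise-floor caveat on the subject effect

The subject-level random effect is *common-mode*: it moves all genes of
a subject together, so no amount of gene averaging removes it. For
planted slopes $s$ (log2/day) and subject effect $\sigma_s$ (natural
log), the induced age error is approximately
$\sigma_s / (s \ln 2)$ days — with the defaults
($\sigma_s = 0.15$, $s = 2/238$) an irreducible floor of roughly
26 days RMSE that no estimator, however good, can beat, because the
offset is indistinguishable from a true age shift. Recovery benchmarks
that target RMSE below this floor are therefore run on cohorts whose
noise model is negative-binomial sampling plus dropout only
(`subject_sd = 0`).

# QC and preprocessing

* `filterCells()` retains cells whose detected (nonzero) gene count lies
  in `[800, 6000]` — the bounds themselves survive, since the filter
  discards strictly below/above — and whose mitochondrial percentage is
  at most 5% (`MT-` prefix, case-insensitive, configurable). The filter
  is idempotent and reports removals per rule.
* `logNormalize()` is the standard library-size normalization:
  counts / cell total × `scale_factor` (default 1e4), then `log1p`.
  Zero-total cells become all-zero with a warning.
* `subsetCellTypes()` keeps annotated types with at least 1000 cells
  ("fewer than 1000" read strictly: exactly 1000 survives).
* `imputeExpression()` is a pluggable hook between normalization and
  scaling. The built-in `knn_smooth` replaces each cell by the mean of
  its k = 15 nearest neighbours (self included) in a 20-PC space of the
  log-normalized layer. Zero-imputation matters for the clock because
  pseudo-cells aggregate by the *median*: a gene detected in fewer than
  half the cells of a group has median zero whatever its level, so with
  heavy dropout the planted signal survives aggregation only after
  smoothing. The hook is an interface — any heavier diffusion-based
  imputation can be dropped in; the clock's correctness properties do
  not depend on the specific smoother. Note that smoothing is applied
  to a whole cell-type subset before the subject split, so test cells
  can contribute to a training cell's neighbourhood; the subject-level
  hold-out evaluation remains label-blind.
* `scaleGenes()` centers and scales each gene to unit sample variance
  and returns the fitted parameters so test data is always transformed
  with training-set statistics. Zero-variance genes map to all-zero
  columns with their scale recorded as 1, keeping the transform
  invertible (round-trip verified to 1e-10).

# Signature scoring

`moduleScore()` implements control-binned gene-set scoring: genes are
ranked by dataset-wide average expression and cut into `n_bins = 24`
equal-frequency bins; for each signature gene, `n_ctrl = 100` control
genes are drawn from its bin (without replacement within a draw, union
deduplicated); the score is the mean expression of the signature genes
minus the mean of the control set. The score is invariant to cell and
gene order and to adding a constant to the whole matrix; ties at bin
boundaries are broken by stable order after ranking, and the seed
governs only the control draw.

Two behaviours worth knowing. First, on a dataset where all per-gene
averages coincide, an up-shifted signature dominates its own expression
bins, the matched controls are then mostly other signature genes, and
the apparent separation collapses; the binned-control design assumes
heterogeneous baseline expression — which real data and the generator
both provide. Second, the converse: with strongly spread baselines the
tail bins are wide, so "gene minus its bin's controls" carries a small
discretization bias even with no signal at all. Null calibration is
therefore sharpest on gene-homogeneous data, and small effect sizes
should not be over-read on real data with extreme expression spread.

`stageCompare()` applies two-sided Wilcoxon rank-sum tests between
pregnancy stages (exact for small tie-free samples, normal approximation
with tie correction otherwise; all-equal data reports p = 1), with the
conventional star thresholds 0.05/0.01/0.001/0.0001. Cells are the
default unit; `unit = "subject"` averages within subject first, a
conservative option when cells are strongly correlated within donor.

`geneAgeCorrelation()` correlates *per-gestational-week mean* expression
with the week number (Pearson, two-sided t-test). Weekly means are the
unit deliberately: correlating per cell would inflate n by orders of
magnitude and make p-values meaningless.

`differentialExpression()` runs per-gene rank-sum tests on normalized
expression with
`log2FC = log2((mean(expm1 g1) + 1) / (mean(expm1 g2) + 1))`,
Benjamini–Hochberg adjustment, and the significance rule
`|log2FC| >= 0.3 & p_adj < 0.05`; marker mode applies the usual
cluster-marker variant (expressed in ≥ 25% of either group, positive
only, log2FC ≥ 0.25).

The shipped `signatures.yaml` carries the cytotoxicity, apoptosis and
exhaustion marker lists plus an editable placeholder ISG list; GO-term
signatures are config-supplied because resolving term membership from an
ontology is out of scope.

# The clock

The pipeline per cell type, in `runClockAllTypes()`:

1. **Split first, aggregate second.** Pregnant subjects are stratified
   by period (early ≤ 13 weeks, middle 14–27, late ≥ 28) and split
   70/30 within stratum; non-pregnant subjects are excluded — the clock
   is a clock of normal pregnancy. Pseudo-cells are then built *within*
   each side, so no aggregate ever mixes train and test cells, and no
   subject appears on both sides (audited over 100 seeds in the tests).
2. **Pseudo-cells.** Within each subject, cells are permuted (seeded)
   and cut into consecutive groups of 10; each group collapses to its
   per-gene median (midpoint convention), leftovers are discarded
   rather than pooled across subjects, so a subject with n cells yields
   floor(n/10) pseudo-cells.
3. **Scaling** is fit on training pseudo-cells only.
4. **Gene selection** is an L1-penalized linear regression of age (days)
   on the scaled matrix at fixed penalty 0.1 in the 1/(2n) RSS
   parameterization; nonzero-coefficient genes are kept, ordered by
   |coefficient|. If shrinkage empties the selection (possible only on
   pathological input), a loudly-logged fallback takes the 50 genes
   most correlated with age.
5. **Forest tuning.** 25 random-search candidates over trees 100–300,
   depth unlimited or 5–30, min node size 1–10, feature fraction
   0.05–0.20 (around the sqrt(p)-to-p/5 conventions) and bootstrap
   fraction 0.5–1, each scored by mean 5-fold CV RMSE on training
   pseudo-cells; the best is refit on the full training side. The space
   is deliberately lean: candidate cost grows as trees × mtry × n log n,
   and this range keeps a full tune on ~800 × ~700 training matrices
   within minutes on one CPU while covering the standard
   regression-forest regimes.
6. **Evaluation.** Each test pseudo-cell is predicted, predictions are
   averaged within subject, and subjects are scored by Pearson R
   (t-test, n−2 df), RMSE in days, and per-period breakdowns. A model is
   *retained* when R ≥ 0.8. Fewer than 3 test subjects, or
   zero-variance predictions, report NA metrics rather than a number.

# Interpretation

`shapValues()` computes exact per-instance Shapley attributions of the
fitted forest with the polynomial-time tree-path algorithm (implemented
in C++ in `src/treeshap.cpp`). The coalition value is the expected tree
output when the coalition's features are fixed and the remainder follows
cover-weighted paths, with covers counted from the training pseudo-cells
(every split side contains at least one bootstrap sample, so covers are
strictly positive). Two properties are enforced by tests: *additivity* —
attributions plus base value equal the forest prediction on every
instance to ~1e-12 — and agreement with a brute-force Shapley
enumeration oracle on small forests to 1e-10.

`shapRank()` ranks genes by mean |attribution| (in days) over the
training pseudo-cells; `selectTopGenesRetrain()` walks the gene-count
ladder {5, 10, 20, 50, 100, 200, all}, scores each top-k set by CV MSE
at the fixed tuned hyperparameters, takes the smallest k at the minimum,
and retrains the final forest; `crossTypePrioritize()` aggregates
per-type importances over genes appearing in at least two models by
unweighted mean (the aggregation is a package choice; flagging genes
present in every model reproduces the headline "shared clock gene"
readout).

# Numerical and design choices

* Stage map: non-pregnant = week 0; first trimester weeks 1–13; second
  14–27; third ≥ 28; an optional substage map splits the first trimester
  at week 9. These are the standard clinical cutoffs.
* Detected genes means *nonzero* genes per cell; QC bounds are read as
  "strictly below 800 / strictly above 6000 discarded".
* Both 800/6000 detected-gene bounds and the ≥ 1000 cells-per-type rule
  are boundary-inclusive on the retained side, which the tests pin down
  explicitly.
* The LASSO penalty is applied with pre-scaled features and the response
  in days; `standardize = FALSE` keeps the penalty's meaning identical
  across cohorts.
* Degenerate inputs are defined, not accidental: zero-total cells
  normalize to zero; zero-variance genes scale to zero; all-equal
  rank-sum input gives p = 1; constant predictions give NA correlation;
  single-subject strata go to training with a warning.
* A single master seed fans out to fixed per-stage seeds
  (`seed * 1000 + stage offset`), so every stage is independently
  reproducible and reruns are byte-identical.
* Problem sizes in the tests: the recovery benchmark uses 100 subjects ×
  120 cells × 1000 genes (50 planted, log2FC 2, NB dispersion 2, dropout
  0.3, no subject effect per the noise-floor analysis above), with
  knn-smoothed normalized expression feeding the clock; unit tests use
  much smaller fixtures sized to make each property sharp.

# Known limitations

* The built-in `knn_smooth` is a simple neighbourhood mean, not a
  diffusion operator; it exists to make the imputation interface real
  and testable, and heavy imputation methods can be substituted.
* Weekly-mean correlations assume enough cells per week for stable
  means; with very sparse weeks the correlation is noisy.
* The cross-type aggregation weights all involving models equally;
  alternative weightings (e.g. by model R) are not implemented.
* Attributions explain the fitted forest, not biology: a high-SHAP gene
  is a gene the model uses, which on collinear inputs need not be the
  causal driver.
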