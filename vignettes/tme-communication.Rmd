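---
title: "Receptor-ligand communication scoring and MxIF quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-ligand communication scoring and MxIF quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmekit)
```

# Scope

`tmekit` implements two analyses for characterizing tumor-microenvironment
interactions — communication between cancer-associated fibroblasts (CAFs)
and tumor or squamous epithelial cells inferred from single-cell RNA-seq,
and CAF-subtype abundance measured from multiplex immunofluorescence (MxIF)
images — together with synthetic-data generators that plant known ground
truth for both. This vignette explains the models, the tunable parameters,
and the design decisions that were genuinely open.

# Expression pipeline

## Quality control

Cells with fewer than 500 genes detected, or with more than 15% of counts on
mitochondrial genes (name prefix `mt-`, mouse nomenclature), are removed.
Both comparisons are strict, so ties — exactly 500 genes, exactly 15% — are
retained; `filter_cells()` is idempotent and reports how many cells each
criterion removed. The 500-gene floor is meant for genome-wide data; the
synthetic studies, whose universe is a 60-gene panel, scale it down to 10
(`rl_study_design()$qc`).

## Normalization

Each cell is scaled to 10,000 total counts and log-transformed in base 2:
$x_{gc} = \log_2(c_{gc} / \sum_g c_{gc} \times 10^4 + 1)$. Base 2 is used
throughout — including all downstream fold changes — so the interaction
score below is an exact sum of log2 fold changes. Zero counts map to exactly
0, and for every cell with nonzero total the inverse transform conserves the
10,000 scale to machine precision (this is asserted in the tests). Cells
with zero total counts (possible after subsetting) normalize to all-zero
columns rather than erroring; in any real run the QC step has already
removed them.

## The hurdle differential-expression test

Single-cell expression is zero-inflated: a gene is either not detected or
detected at some positive level. `hurdle_test()` therefore models the two
parts separately, each with versus without a group (foreground/background)
indicator:

- **Discrete part.** Detection ($x > 0$) as binomial; the likelihood-ratio
  statistic has a closed form in the 2×2 detection table.
- **Continuous part.** The positive values as Gaussian with a common
  variance; the LR statistic is $n \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)$.

The two statistics are summed and referred to $\chi^2_{df}$ with one degree
of freedom per component actually fitted. No cellular-detection-rate or
other latent covariate is included: the minimal two-part model keeps the
test interpretable and, as the calibration study shows, its null p-values
are uniform at the sample sizes the pipeline works with. Degenerate inputs
are resolved explicitly rather than by letting a fit fail: a gene undetected
in both groups returns $p = 1$; all-positive input drops the discrete part;
positive values constant within groups (zero residual variance), fewer than
three positives overall, or positives confined to one group drop the
continuous part.

Strata with fewer than 3 cells (configurable) are not tested at all — a
logistic or Gaussian fit on one or two cells is meaningless — and are
emitted with $p = 1$ and `status = "too_few_cells"`.

## Fold changes

`log_fold_change()` works on the linear scale with a pseudocount:
$\mathrm{log2FC} = \log_2(\bar{y}_{fg} + 1) - \log_2(\bar{y}_{bg} + 1)$
where $\bar y$ is the mean of $2^x - 1$ (the normalized linear expression).
The pseudocount keeps every fold change finite — important downstream, where
the interaction score is a log of a product of fold changes and must never
see a nonpositive argument. The cost is shrinkage toward zero for genes
whose normalized mean expression is comparable to the pseudocount; the
recovery studies therefore give designated genes a moderate baseline so the
planted effect is identifiable (see *Synthetic data*).

## Stratification and the background

Differential expression is computed per (cell type, sample) stratum against
the pooled complement: all other cell types **and** all other samples. Two
consequences are worth understanding:

- The phrase "all other cell types and samples" admits a second reading —
  background restricted to the same condition group. Both are implemented
  (`background = "all"` is the default; `"within_group"` is the switch);
  the all-pool reading is the default because it is the literal one.
- When an effect is planted in one cell type across *all* samples of a
  group, the background of each affected stratum still contains that cell
  type's cells from the sibling samples, so the measured contrast is
  attenuated: under the default design (5 cell types × 5 samples, equal
  strata, 4-fold effect in 3 samples) the expected measured log2FC is
  $\log_2(4 / 1.25) \approx 1.68$ rather than 2. This is a property of the
  estimator, not an artifact: the recovery study for fold-change accuracy
  (`study_de_recovery()`) plants each designated gene in a *single* stratum
  so the estimand equals the planted value, while the interaction-recovery
  study keeps group-wide planting and relies on the (much looser) filter
  thresholds.

## Multiple testing

All (gene, cell type, sample) p-values in a table are adjusted as one
Benjamini–Hochberg family (`adjust_pvalues()`, a validating wrapper over
`stats::p.adjust`); per-stratum adjustment is available behind
`family = "per_stratum"`.

# Interaction scoring

The prior-knowledge network is a directed ligand→receptor edge list with a
mode-of-action column; on loading it is subset to edges with known
directionality and known mode, and duplicate pairs are collapsed. Mode
(stimulation vs inhibition) is carried through to the output but never
changes the score's sign: only the subsetting is part of the procedure, and
silently negating inhibitory scores would conflate curation metadata with
measured expression. Edges are evaluated in the ligand→receptor direction
only: the sender expresses the ligand, the receiver the receptor.

For each edge and sample, `RL = log2FC_ligand + log2FC_receptor`, which is
exactly $\log_2(FC_L \times FC_R)$ on linear fold changes — computed as a
sum to avoid any double-logging ambiguity, and asserted as an identity on
every record. Because the per-sample scores are what the consistency filter
inspects, both per-sample records and a group aggregate (arithmetic mean of
per-sample scores) are emitted.

The significance flag is deliberately conservative: an edge is flagged only
when **every** sample of the group satisfies all four conditions (both
adjusted p-values < 0.01; ligand log2FC ≥ 0.5, an inclusive bound; receptor
log2FC > 0, an exclusive bound — "positive"). A missing stratum in any
sample permanently blocks the flag. Only the ligand carries an effect-size
bound beyond positivity; the receptor's bound is positivity itself. All
records are retained whether flagged or not, so a score table can be drawn
in full with stars marking the flagged edges.

# MxIF quantification

Each marker channel is thresholded into a binary mask (`threshold_channel`);
pixels strictly above the threshold are positive. The thresholding rule is
recorded in the mask's provenance whether it was fixed by the user or
selected automatically (Otsu's bimodal-histogram method via
`EBImage::otsu`); automatic selection on a constant channel errors with a
pointer to the fixed-threshold override, rather than inventing a cut.

CAF subtypes are defined by marker co-expression — CAF1 = SMA⁺VIM⁺,
CAF2 = PDGFRα⁺TNC⁺ — so "overlaying" the two marker masks is implemented as
their **intersection** by default: a pixel must be positive for both
markers. Union is available (`combine = "union"`) since the looser reading
is also defensible; the choice is recorded in the output provenance.

The tumor region is the thresholded β-catenin mask itself; no morphological
cleanup is applied by default, keeping the mapping from thresholds to areas
exact and auditable. Abundance is
$|\mathrm{CAF mask} \cap \mathrm{tumor mask}| / |\mathrm{tumor mask}|$,
which is invariant to anything outside the tumor region and bounded in
$[0, 1]$. Group comparisons use the pooled-variance Student's t-test with
$df = n_x + n_y - 2$; zero-variance degeneracies return $p = 1$ (equal
means) or $p = 0$ with a warning (unequal means).

# Synthetic data

## Counts

`simulate_counts()` draws NB counts with mean
(gene baseline) × (per-cell log-normal scaling) × $2^{\text{planted log2FC}}$
and size `dispersion`, then zeroes entries by a dropout step. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 60 | gene panel incl. 5 `mt-` genes |
| `cell_types` | CAF1, CAF2, tumor, squamous, other | TME-like mixture |
| `groups` | 3 + 2 samples | two-condition replicate design |
| `baseline_mean` | 2 | NB mean scale (counts/cell/gene) |
| `baseline_sdlog` | 1 | log-normal spread of gene baselines |
| `dispersion` | 2 | NB size; var = μ + μ²/2 |
| `library_size_spread` | 0.3 | sdlog of per-cell scaling |
| `dropout_midpoint`, `dropout_slope` | 1, 1 | logistic dropout vs log2 baseline |

The 3 + 2 replicate structure mirrors the two-condition mouse design the
replicate-consistency filter was built for. Depth and dropout defaults are
chosen for testability — moderate expression, roughly 30–50% zeros — not
fitted to any particular platform; the generator makes no attempt to model
doublets, batch effects, or ambient RNA, so passing tests demonstrate
correctness of the computations, not robustness to those artifacts.

Two deliberate design choices:

- **Dropout is a gene-level property.** Each gene's zeroing probability
  comes from a logistic curve in its log2 *baseline* mean and is applied
  uniformly across cells. Making dropout depend on the per-cell mean
  (including planted effects) would systematically inflate recovered fold
  changes — an elevated gene drops out less, so the measured ratio exceeds
  the planted one by ~0.5 log2 units under the default curve — leaving no
  well-defined ground truth to recover. With gene-level dropout,
  linear-mean ratios between populations are exactly the planted ratios.
- **Planted genes get a fixed baseline.** Genes named in `planted_effects`
  take the configured `baseline_mean` exactly instead of a log-normal draw:
  the pseudocount in the fold-change definition shrinks low-expression
  genes, so a designated gene landing in the tail of the baseline
  distribution would have a planted effect that is not recoverable even in
  principle. Fixing the baseline makes "planted log2FC = 2" a well-defined
  target (the shrinkage at baseline 2 is < 0.03 log2 units).

With the default panel the five mitochondrial genes carry a noticeable and
seed-dependent share of counts, so the 15% QC rule genuinely removes cells
in the synthetic studies (roughly a third of cells at the default seeds) —
the QC stage runs against real resistance rather than being a no-op.

## Priors and images

`simulate_interaction_prior()` emits the designated true edges plus decoy
edges between unperturbed genes, all directed with known mode, and
optionally extra modeless rows that the loader must drop.
`simulate_mxif_image()` paints rectangles and discs into mapped channels
(overlaps take the pixelwise maximum), adds Gaussian noise clamped at zero,
and returns the exact painted pixel sets and analytic abundances as ground
truth.

# Study sizes and numerical choices

The seeded studies behind the tests and the acceptance script use: 1,000
independent null replicates of 2 × 200 cells for type-I calibration (each
replicate is a fresh simulation, because testing many genes of one data set
would correlate the p-values through shared library sizes); 500 cells per
stratum for the fold-change and interaction recovery studies (25 strata,
~12,500 cells, 60 genes); and 128 × 128-pixel images with signal 100, noise
sd 0 or 10, and a half-signal threshold of 50 for mask recovery. These sizes
put Monte-Carlo error well inside the tolerances asserted (fold-change
recovery error ≲ 0.15 against a 0.3 band; rejection rates within ±0.015 of
0.05) while a full suite run stays comfortably under a minute.

Other numerical details: likelihood-ratio statistics are clamped at zero
(finite-sample roundoff can produce tiny negative values); BH adjustment is
permutation-equivariant and never below the raw p-value; image intensities
written to TIFF are scaled into [0, 1] by a recorded factor because float
TIFF storage is undefined outside that range.

# Known limitations

- The hurdle test's χ² reference is asymptotic; below a few dozen cells per
  stratum the discrete component is visibly discrete and p-values become
  conservative. The `min_cells` floor guards only against degeneracy, not
  against low power.
- The pooled background means group-wide effects are attenuated (see above);
  users comparing measured log2FCs against external expectations should
  account for the background composition.
- The image pipeline quantifies areas only: no segmentation, registration,
  illumination correction, or spatial statistics.
- Thresholds for real MxIF images are a scientific choice; Otsu is a
  reasonable default for bimodal channels but every threshold should be
  reviewed via the recorded provenance.
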