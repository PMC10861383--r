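---
title: "Metabotype screening in crossover provocation trials: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabotype screening in crossover provocation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotypeR)
```

`metabotypeR` asks a deceptively simple question of a three-arm crossover
provocation trial: do subgroups of participants ("metabotypes") exist
whose symptom response to FODMAPs or gluten is predictable from baseline
molecular data, or from the metabolite dynamics of a rapid provocation
test? This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-trial generator does and does
not emulate, and the design choices made where the methodology was
genuinely open.

## The trial structure being modelled

Each subject completes week-long FODMAP, gluten and placebo exposures in
randomized order, each preceded by a washout week. Symptoms are scored
with the IBS severity scoring system: five visual-analog items (pain
severity, pain frequency, distension, bowel dissatisfaction, life
interference) on 0–100, summed to a 0–500 total; totals below 175 are
mild, 175–300 moderate, above 300 severe, and an increase of strictly
more than 50 points over washout is the conventional clinically
significant change. Baseline molecular blocks are genus-level microbiota
relative abundances (compositional: rows sum to 1), fecal and plasma
short-chain fatty acid concentrations, untargeted plasma metabolome
intensities (positive), and a mixed clinical/questionnaire table. A
separate rapid provocation test yields a subjects × features ×
8-timepoint metabolome tensor (draws at −10, 0, 10, 20, 30, 90, 150 and
240 minutes).

## Response representations and the clustering grid

Every IBS-SSS variable (five items and the total) is screened under
three representations against the preceding washout week: the absolute
intervention-week value, the difference, and the log2 fold change. The
fold change uses an additive guard of 1 on both scores so that a 0-vs-0
week yields 0 rather than an undefined ratio; base 2 matches the
log-ratio convention used for the metabolome representations. Whether
the original analysis used natural or base-2 logs for symptom scores is
not documented anywhere we could anchor to; the base does not change any
ordering, only the scale of one representation.

Candidate metabotypes are partitions of the subjects × 3-arm condensed
response frame over a fixed grid: hierarchical clustering on Euclidean
distances and k-means, each on scaled (per-column z-score) and unscaled
data, at k = 2, 3, 4 — a grid of 6 × 3 × 2 × 2 × 3 = 216 assignments.
Solutions with any cluster below 8 participants are ineligible.
Eligible solutions are randomly downsampled to equal cluster sizes
before classification so the no-information rate is exactly 1/k.

Two details of the grid are deliberate package choices rather than
documented protocol: the hierarchical linkage criterion (complete
linkage, the common default of the R clustering stack this methodology
grew out of) and the k-means initialization (Lloyd updates, 25 seeded
random restarts, best within-cluster sum of squares). Both are exposed
as arguments; determinism under a fixed seed is a hard contract because
every downstream count depends on it.

## The rdCV random-forest screen

The supervised engine is repeated double cross-validation around a
random forest. Within one repetition the subjects are split into
`nOuter` (default 6) outer segments. For each held-out segment, the
remaining data run a recursive variable-elimination ladder: `nInner`
(default 5) inner folds are fitted per step, variables are ranked by
mean out-of-bag permutation importance (impurity importance biases
toward many-valued variables in mixed clinical blocks), and a
`keepRatio` (default 0.75) fraction survives to the next step. Every
step whose mean inner error lies within 5% of the error range of the
minimum counts as optimal; the reported "mid" model size is the rounded
geometric mean of the smallest and largest optimal counts, and a forest
of that size predicts the outer hold-out. Pooled out-of-fold
predictions give the repetition's fitness — Q² for regression, CR for
classification — and the mean over `nRep` repetitions is the headline
number, filtered at the a priori thresholds Q² > 0.2 and CR > 0.6
(twenty percent better than chance).

Models passing the filter face a permutation test: the full rdCV is
re-run on permuted responses and p = (1 + #{permuted ≥ observed}) /
(1 + n_perm), the plus-one estimator that cannot return zero. Because
downsampling discards subjects at random, passing classification models
are additionally re-fitted five times with fresh downsamples and
reported as mean CR ± SD.

The enumeration is part of the method's identity and is reproduced
exactly: 270 regression configurations (6 variables × 3 representations
× 3 arms × 5 predictor sets: microbiota, SCFAs, metabolome, clinical,
combination) and 864 classification configurations (216 grid cells × 4
predictor sets). The combination block in the classification screen
excludes the clinical table — that decomposition (864 = 216 × 4 while
270 = 54 × 5) is the only reading consistent with both counts, and we
adopt it while noting it is inferred from the combinatorics, not from
prose. The provocation screen likewise enumerates 23 tensor
representations (8 timepoint slices, the trapezoidal AUC over −10 to
240 min, 7 log2 ratios against the pre-test draw, 7 pre-test + later
slice pairs) × 3 arms = 69 regression models of the absolute total
score; restricting to the total is again the only decomposition that
reproduces 69.

Two numerical conventions worth knowing: missing predictor cells are
median-imputed per feature before the screen (tree learners are
insensitive to crude location imputation), and the per-block
standardization inside the combination predictor set changes nothing
for the forest itself (trees are scale-invariant) but keeps the
concatenated matrix interpretable.

## PARAFAC temporal metabotyping

The provocation tensor is completed by iterative truncated-SVD matrix
completion on the subject × (feature, time) unfolding: missing cells
start at their subject-feature fiber mean, the matrix is reconstructed
at rank 5 (configurable; no rank is documented for the original tool)
with observed cells restored each pass, until the relative change drops
below 1e-6. A fiber with no observed timepoint is an error, not a
guess.

Two preprocessing schemes are supported: scaling each feature's
unfolded vector to standard deviation one, and subtracting each
subject's global metabolite average before scaling each feature to
root-mean-square one. The phrase "global metabolite average per
individual" is ambiguous between one mean per subject and one per
subject-timepoint; we default to the former and expose the latter
(`centerScope = "subject_timepoint"`).

PARAFAC itself is fitted by alternating least squares over the three
unfoldings. Convergence is declared when the residual sum of squares
changes by less than `tol = 1e-8` of the total sum of squares — scaled
to the total, not the previous residual, so the criterion remains
meaningful as the residual approaches machine zero on noise-free
tensors; `maxIter = 500` flags but does not raise. The indeterminacies
are pinned down at exit: feature and time loadings unit-norm (magnitude
in the subject scores), the largest-magnitude element of each time and
feature loading positive, components ordered by decreasing magnitude.
SVD initialization is the deterministic default; random initialization
is kept for degeneracy diagnostics, and a triple-cosine below −0.85
between two components triggers a degeneracy warning. No
non-negativity or orthogonality constraints are imposed.

Component subject-scores are clustered with the same grid settings and
linked by one-way ANOVA to every IBS-SSS variable in every arm
(absolute values). Over models with 2–20 components one clustering
approach yields Σ₍C₌₂₎²⁰ C × 3 k-values × 3 arms × 6 variables = 11,286
candidate models; whether the original count excluded under-sized
solutions before or after testing is not documented, so results are
flagged ineligible but retained and both counts are reportable. Per-arm
counts of nominal hits are compared with a chi-square goodness-of-fit
against equal expectation: enrichment in an active arm relative to
placebo would be the signature of genuine treatment-specific structure.

Metabolite stability over the test is the ICC(2,1) of each feature's
subjects × 8-timepoint matrix — the two-way random-effects,
single-measure, absolute-agreement intraclass correlation — computed on
log intensities by default (whether the original used raw or log
intensities is unstated; the flag is exposed).

## The synthetic-trial generator

The generator is the package's evidence base, so its mechanics matter.
Defaults mirror the analyzed cohort the framework targets: 74 subjects,
132 genera, 9 SCFAs in two matrices, a high-dimensional metabolome
(500 features at desk scale against thousands in a real study), 24 + 6
clinical variables (scaled down from the ~124 of a full questionnaire
battery; only dimensionality matters to the screens), and the 8-draw
schedule.

Symptoms arise from a per-subject latent severity, normal with mean 250
and sd 60 truncated to the 0–500 total scale — a moderate-to-severe IBS
cohort — apportioned to the five items by a subject-specific
Dirichlet(2,2,2,2,2) split, which preserves the total scale and induces
realistic positive item correlation; no item-level generative model
exists to copy. Each arm × week record adds occasion noise (default
sd 30 points, the scale of week-to-week fluctuation that makes a
50-point change the clinical yardstick), planted metabotypes add their
per-class, per-arm response shift to the intervention week, and items
are clipped to bounds afterwards. Washout weeks draw from the same
latent severity without any treatment shift: the washout is the
reference in every representation, and nothing beyond that reference
role is documented, so the simplest exchangeable model is used and
flagged as a modelling choice — in particular, within-subject
correlation of responses across arms is whatever the shared latent
induces, not a fitted quantity.

Molecular blocks are log-normal (logistic-normal with closure for the
microbiota, so rows sum to 1 even after planted shifts), and planted
molecular effects are standardized mean shifts on the log scale applied
to configured feature subsets. The provocation tensor is a planted sum
of `tensorRank` rank-1 components with log-normal factors (positive
intensities) or orthonormalized factors with distinct magnitudes for
recovery tests; noise is scaled to the signal RMS and a configurable
fraction of cells is masked uniformly (exactly ⌊rate · n·p·t⌋ cells; a
mask drowning an entire fiber is rejected). Every block draws from its
own named RNG stream derived from the master seed, so resizing one
block never perturbs another — a contract the tests assert.

What the generator does *not* emulate: 16S read counts or sequencing
noise, chromatograms or LC-MS peak shapes (blocks are generated at the
processed-feature level), batch effects, dropout or missing arms,
nocebo dynamics, or any dependence of molecular blocks on symptoms
beyond the planted shifts. Passing screens on synthetic data therefore
demonstrate that the machinery recovers structure it was built to
represent and stays calibrated under its null — not that real trials
contain such structure.

## Problem sizes and calibration checks

The validation suite runs at desk scale, chosen so the full set of
checks completes in minutes on one CPU: calibration uses 20 global-null
trials (n = 74, 200 metabolome features) and 20 planted-signal
replicates (two classes, standardized shift 2.0 on 10 of 200 features,
n = 40), each with 20-permutation tests, fitted with a single
repetition and no variable elimination — the permutation test is valid
for any fixed modelling procedure, and the ladder multiplies cost
roughly a hundredfold without changing the calibration question.
Tensor recovery uses a noise-free rank-3 74 × 200 × 8 tensor. The full
protocol (5 repetitions, 100 permutations, variable selection on) is
restored by `paperScale = TRUE` in `runPipeline()`.

Known limitations: rdCV fitness of a random forest on a strongly linear
signal saturates below the linear-model ceiling (forests do not
extrapolate, and out-of-fold predictions shrink toward the mean), so
recovery tests anchor to a forest oracle fitted on the true variables
rather than to an absolute Q²; the exhaustive Fisher path is used for
2 × 2 and small r × c tables with a seeded Monte-Carlo estimate beyond;
and the linkage screen's p-values within one dataset are mutually
dependent (shared responses and labels), so uniformity under the null
is a statement about independent replicates, not about the 11,286
values of a single run.
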