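---
title: "Quantifying G0 arrest from transcriptomes: models and design choices"
author: "g0kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying G0 arrest from transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g0kit)
```

## The problem

A subpopulation of tumour cells can exit the cell cycle into a
reversible, non-proliferative G0 state (quiescence). These cells lack a
single measurable marker — absence of proliferation markers does not
distinguish G0 from a long G1 — but they leave a coordinated
transcriptional footprint: a set of genes consistently up- or
downregulated across distinct quiescence-inducing conditions
(spontaneous arrest, contact inhibition, serum starvation, CDK4/6
inhibition, MEK inhibition). `g0kit` turns such a gene signature into
per-sample and per-cell G0-arrest scores, classifies the inducing stress
programme, models genomic features associated with arrest propensity,
and reduces the signature for sparse single-cell data. Every stage has a
matching synthetic-data generator with known ground truth, so the whole
pipeline is testable without any external cohort.

## Signature construction

`refineSignature()` starts from a differential-expression table covering
the five quiescence forms and applies, in order: (0) significance in all
five forms (`padjCut`, default 0.05); (1) a unidirectional fold-change
sign across forms; (2) an explicit exclusion list (genes acting in other
cell-cycle stages); (3) removal of genes with low variability or low
expression in a reference cohort, and of genes weakly correlated with
the mean expression of the DREAM-complex transcriptional targets, the
central repressor driving G0 entry. The published thresholds for step
(3) are not stated anywhere we could rely on, so the package defaults
are explicit, conservative choices: genes below the 10th cohort
percentile of per-gene SD or mean expression are "low", and the DREAM
correlation gate is |r| < 0.3 against the target-set mean expression
(computing the reference as mean target expression rather than a
derived DREAM activity score is itself a choice; both are exposed as
arguments). Filters (1)–(3) are order-independent and idempotent, which
the test suite checks.

`buildStressSignatures()` builds the five programme-specific signatures:
per form, significance for that form only, filters (2)–(3), then the top
10 genes per direction by |log2FC|. Ties at the boundary break
alphabetically so results are reproducible.

The vendored files under `inst/extdata/` (`g0_139_synthetic.tsv`,
`g0_35_synthetic.tsv`, `housekeeping_synthetic.tsv`) are synthetic
stand-ins carrying the correct cardinalities (139, 35, 30 genes) with
placeholder identifiers; they exercise every code path and size
invariant but are not curated biology. Users analysing real data should
substitute curated lists.

## Scoring

The primary score is the combined Z-score: per gene, expression is
standardised across samples (sample SD, n−1); per sample, standardised
values are summed over the up-set and divided by the square root of the
number of genes used, likewise for the down-set, and the final score is
the up-score minus the down-score. Higher always means more arrested.
Signature genes absent from a dataset (dropout) are silently excluded
and reported in the score object (`nUpUsed`, `nDownUsed`); zero-variance
genes contribute 0 and are excluded from the square-root normaliser, so
a constant gene cannot dilute the score. The score is invariant under
any positive gene-wise affine transform, which makes it insensitive to
per-gene scale and offset differences between platforms.

Two comparators are included: the mean-scaled score
`G0m = (mean(G_U) − mean(G_D)) / mean(G_H)` with a housekeeping set
`G_H` (scale-invariant on the linear scale; housekeeping genes
overlapping the signature are excluded at scoring time), and a simple
normalised mean-rank difference (`rankScore()`), which serves as a
rank-based reference point rather than a reimplementation of any
published rank method.

Bulk cohorts are adjusted for tumour purity before scoring: samples
below 30% purity are removed, and remaining expression is divided by
purity on the linear scale (log2 values are exponentiated, divided, and
re-logged). The mechanics of purity scaling are under-specified in the
literature this follows; division on the linear scale is the
interpretation implemented, and `mode = "none"` applies only the
filter. Classification into arrested/proliferating uses a strict
threshold (default 0, the natural midpoint of the combined Z-score);
`kmeansHighLow()` offers the cohort-level alternative — k-means with
k = 2 on the signature-gene submatrix after batch adjustment, the
higher-scoring cluster labelled "high" (Lloyd's algorithm, 25 seeded
restarts). Classifier quality is measured by ROC AUC in the rank
(Mann–Whitney) formulation with mid-rank tie correction, which the
tests verify against pair-counting and trapezoidal-integration oracles.

### Batch adjustment

Where tissue or study effects must be removed (k-means grouping, kNN
reference mapping), the package uses per-batch location–scale
standardisation of each gene mapped back to the pooled mean and SD.
This is a deterministic adjustment without empirical-Bayes shrinkage of
batch parameters: it removes additive and multiplicative batch offsets
exactly, needs no hyperparameters, and is sufficient for the planted
offsets the generators produce. It will under-perform empirical-Bayes
methods on very small batches of real data, a known limitation.

## Stress-response subtyping

`scoreStressProgrammes()` scores the five programme signatures and the
generic signature. Bulk subtype assignment follows a conservative rule:
samples without generic arrest evidence (generic score ≤ 0) are
"uncertain"; otherwise the top-scoring programme is assigned only if its
score exceeds the cohort mean plus one cohort SD for that programme and
a two-sided Welch t test finds its per-gene z contributions
significantly higher (α = 0.05) than the pooled contributions of the
other four programmes in that sample. A per-sample t test between
programme *scores* is not well defined — a sample has one score per
programme — so the test operates on the per-gene contributions, the
only within-sample replicates available; this interpretation is a
design decision of the package.

Single cells are classified by reference mapping: shared genes,
location–scale batch adjustment between query and reference, PCA on the
combined matrix (centred, not re-scaled, since genes are already
standardised; fitting on the combined rather than reference-only matrix
keeps query and reference in one coordinate system), then k-nearest
neighbours among the reference points with k = 3 and a 2-vote rule;
neighbourhoods without a 2-vote class return "uncertain". Distance ties
break by reference order for determinism; `nPcs` defaults to 10 and is
clipped to the available rank.

## Genomic dependency modelling

Driver prioritisation uses Fisher's exact test per binary feature
against the high/low arrest grouping with Benjamini–Hochberg correction
(q < 0.05); the reported odds ratio is the sample odds ratio
(Haldane-corrected on zero cells). The central model is an ensemble
elastic net: samples with fewer than 50 mutations are removed, the
response is regressed on genomic features 1000 times (100 at desk
scale), each time on a random 90% subsample, and only features with
nonzero coefficients (|coef| > 1e−8) in *every* iteration form the
consensus; their coefficients are averaged into a linear consensus
model whose intercept makes it exact at the training feature means.
Continuous covariates are standardised; binary events stay 0/1;
categorical covariates enter one-hot.

Two tuning choices matter and are deliberate:

* **Mixing/penalty selection happens once per ensemble** (10-fold CV
  over mixing 0.1–1.0 with glmnet's automatic penalty path), then the
  chosen pair is reused across subsample iterations. Re-tuning inside
  every iteration is an order of magnitude slower and makes
  iteration-to-iteration selection variability reflect tuning noise as
  well as subsampling, which is what the consensus intersection is
  meant to measure. `tuning = "per_iteration"` restores per-fit tuning.
* **The penalty uses the one-standard-error rule** (`lambdaRule =
  "1se"`). At the CV-minimising penalty, a marginally correlated null
  feature can remain nonzero in every subsample and contaminate the
  consensus; the 1se rule is the conventional parsimony choice and
  keeps the consensus specific to reproducible effects.
  `lambdaRule = "min"` is available.

Feature attributions use the exact Shapley solution for linear models
under the independent-features convention,
`phi = coef * (x − mean)`, which is additive by construction and is
verified in the tests against exhaustive permutation enumeration. The
tissue-specific variant (`anovaRfTissueModel()`) screens features by
one-way ANOVA F statistic, keeps the top 30, and averages random-forest
accuracy over five stratified 80/20 splits (500 trees).

## Signature reduction for sparse single-cell data

`giniImportance()` trains repeated random forests (500 trees; `nRep`
defaults to 100 at desk scale, 1000 reproduces the full procedure) per
training dataset to predict cell state from the signature genes,
averages per-gene Gini importance over repetitions, and min–max
normalises within each dataset. Averaging before normalising (rather
than normalising each repetition) was chosen because it weights stable
importance over run-to-run extremes. `thresholdSweep()` forms candidate
subsets — genes above threshold in at least one dataset, sweeping 0 to
1 in 0.01 steps, duplicates collapsed onto the smallest threshold — and
`validateSubsets()` scores each candidate on a validation cohort and
correlates it with experimental quiescence measurements.

Candidate selection among near-tied correlations is genuinely open, and
a raw argmax is noise-driven: at a validation size of a few dozen
samples, all-informative subsets of different sizes have statistically
indistinguishable correlations, and the argmax lands arbitrarily.
The package therefore shortlists candidates whose primary-assay
correlation lies within one Fisher-z standard error of the best and
returns the *largest* of them: at equal demonstrated performance, more
genes hedge against single-cell dropout, which is the reason the
reduction exists. A significance gate (p < 0.05 on the mean assay
correlation, Fisher z) filters candidates first.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their configuration and a seed;
one user seed fans out into named per-component streams so
sub-simulations are independently reproducible.

* `simulateBulk()` / `simulateSingleCell()`: Gaussian log2 expression
  (gene baselines N(5, 2), measurement noise SD 1), a planted
  two-state population (default 200 samples, arrest fraction 0.5,
  ±3 log2 shift on signature genes), optional additive batch offsets,
  Beta-distributed purity with linear-scale mixing against a fixed
  normal profile, and i.i.d. Bernoulli dropout (default 20%) for the
  single-cell variant.
* `simulateStress()`: one of the five programmes per arrested cell
  (±2 shift on that programme's genes; 100 cells per programme), a
  generic-arrest shift shared by all arrested cells, a pool of
  unshifted cycling cells, and per-programme bulk reference profiles.
  The cycling pool matters: the combined Z-score is cohort-relative,
  so a cohort containing only arrested cells centres the generic score
  at zero and the generic-evidence gate of the bulk rule would be
  uninformative.
* `simulateGenomic()`: Bernoulli(0.3) binary events, a linear response
  with planted coefficients (default 2 and −1.5 against 40 nulls,
  noise SD 0.5, n = 500) and mutation counts placing a configurable
  fraction below the 50-mutation filter.

These generators emulate shift, dropout, batch, purity and planted
linear structure — not library-size effects, count overdispersion,
gene–gene correlation, or cell-type mixtures. Passing tests therefore
demonstrate that the algorithms recover the structure they claim to
recover under controlled conditions; they do not certify performance
on any real cohort.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen once: 200
samples/cells for scoring checks, 100 cells per programme for
subtyping, n = 500 with 100 ensemble iterations for the genomic model,
three 120-cell training datasets with 100 forest repetitions for the
reduction, and 20 (or 10) seeds for stochastic claims. Nonzero
coefficients are |coef| > 1e−8; Shapley additivity is exact to
floating-point (≈ 1e−16 observed, asserted at 1e−10); zero-variance
genes are flagged rather than dropped silently; k-means uses a fixed
seed parameter and 25 restarts; all log/linear conversions use log2.

## Limitations

The location–scale batch adjustment does not shrink small-batch
estimates; the purity-scaling interpretation (division on the linear
scale) is one of several defensible readings; the bulk subtype t test
on per-gene contributions is an interpretation of an under-specified
rule; the vendored signature files are placeholders; and none of the
validation here involves real tumour data.
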