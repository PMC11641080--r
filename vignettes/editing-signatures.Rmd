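---
title: "Methods: blood RNA-editing signatures for psychiatric diagnosis"
author: "editsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood RNA-editing signatures for psychiatric diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editsig)
```

This vignette is the package's account of the statistical procedures it
implements, the choices made where the design was genuinely open, and what
the synthetic-data tests do and do not demonstrate.

## The measurement model

A-to-I editing at a site appears in sequencing reads as an A→G substitution
(or T→C on the reverse-sequenced strand). For a site covered by `n` reads
with `g` edited and `a` reference calls, the editing fraction is
`g / (a + g)`; bases other than the reference/edited pair (sequencing
errors, N) are excluded from the denominator rather than counted as
unedited. Quality control operates at two depths: a per-sample floor of
10,000 aligned reads (samples below it contribute only missing values) and
a per-site floor of 50 informative reads. The per-sample floor is a
published protocol constant; the per-site floor is this package's own
default, chosen so that binomial noise on a fraction of 0.1 stays below
±0.13 at 3σ, and is configurable (`qc_config()`).

Three biomarker kinds derive from the same reads:

* **sites** — the per-site fraction above;
* **isoforms** — per-read joint binary editing patterns over a gene's
  sites. Reads lacking a clean call at any site are excluded (and counted);
  pattern frequencies sum to one per sample, and the marginal fraction of a
  site equals the summed frequency of patterns edited there. This identity
  is asserted exactly in the tests.
* **motifs** — the mean fraction over a declared group of sites. The
  operational definition of both motifs and the background filter is a
  package choice (the source protocol leaves them to supplementary
  material): a biomarker whose cohort-median value is at or below 0.005 is
  treated as background and dropped; the threshold is configurable and a
  zero threshold disables the filter.

Global-editing normalization divides each biomarker of a gene by the
pooled fraction `sum(edited) / sum(edited + reference)` over the gene's
sites, making values relative to overall editing activity. When only a
value matrix is available (no counts), the mean of the gene's site
fractions stands in, which is exact for equal site depths. Normalized
values feed the mROC signatures; the random forest consumes raw fractions
so that the Monte-Carlo generator's logit-scale model stays well defined
on proportions.

## Feature selection

The cascade runs cheapest-first: (1) a univariate filter keeps biomarkers
whose smallest raw p over the six pairwise group comparisons is ≤ 0.05,
using an adaptive test — Shapiro–Wilk normality in both groups at α = 0.05,
then an F-test of variance equality at α = 0.05 choosing Student's versus
Welch's *t*; otherwise the two-sided Mann–Whitney test with tie correction.
The two gate levels are package defaults (the protocol names the tests but
not the gates). (2) Correlation pruning scans pairs in deterministic
row-major order; above |r| = 0.6 the member with the larger mean absolute
correlation to all other features is removed, ties removing the later
column — a deterministic restatement of `caret::findCorrelation`'s
behaviour. (3) Shadow-feature selection: each run appends one permuted
copy per surviving feature, fits a random forest, and scores a hit for
features whose permutation importance exceeds the maximum shadow
importance; two-sided binomial tests of hits against 0.5, Bonferroni
corrected over the still-undecided features, confirm or reject; features
undecided after 100 runs are Tentative and treated as not selected
(conservative and reproducible). Mutual information with the class labels
(equal-frequency binning into `⌈n^(1/3)⌉` bins, plug-in estimate in nats)
is recorded for ranking only — no MI threshold is applied, since none is
published. Selection is performed once on all four classes jointly; the
same selected list serves every downstream comparison.

Benjamini–Hochberg adjustment is the standard step-up rule (via
`p.adjust`). One property often claimed of it — idempotence — is false for
distinct p-values (re-adjusting strictly increases non-maximal values), so
the package's invariants are monotonicity and `adjusted ≥ raw` only.

## Target Editing Index and mROC signatures

For two groups with means `μ₀, μ₁` and covariances `S₀, S₁`, the linear
combination maximizing the binormal ROC area (Su–Liu) is
`a ∝ (S₀ + S₁)⁻¹ (μ₁ − μ₀)`, normalized here to unit L2 norm and oriented
so cases project at least as high as references. When the pooled
covariance is ill-conditioned (condition number above 1e10, e.g. more
features than samples), a ridge `1e-6 · trace(S)/p · I` is added and a
warning notes the optimistic regime. Under equal-covariance Gaussian data
the combination's AUC is `Φ(√(δᵀ(S₀+S₁)⁻¹δ))`, which the acceptance suite
verifies to ±0.01 at n = 20,000.

The per-gene **TEI** z-scores the gene's selected variants, fits the
combination on controls versus all patients pooled (the fitting split is
not published; `reference` exposes the choice), and applies a Box-Cox
transform: shift `max(0, 1e-6 − min)`, λ by profile-likelihood grid search
on [−2, 2] in steps of 0.01, `(x^λ − 1)/λ` with the natural log at λ = 0.
Because the transform is strictly monotone, rank statistics (Mann–Whitney,
empirical AUC) are exactly invariant to it — asserted as an identity in
the tests. Group differences are tested per gene within each pairwise
comparison and BH-adjusted across genes, flagged at FDR < 0.10.

The six **virtual markers** Z1–Z6 (CTRL|BD, CTRL|SZ+SA, BD|SZ+SA, CTRL|SZ,
CTRL|SA, SZ|SA) use all selected biomarkers, globally normalized, fitted
and reported on the full comparison sample with no internal
cross-validation — deliberately mirroring the published analysis, and
therefore optimistic; the reported numbers are training-set performance.
The operating point maximizes Youden's J (ties resolved to the smaller
cutoff; the published tables name no cutoff rule), and predictive values
follow Bayes' rule at the observed prevalence unless one is supplied.

## Integrated random forest

The selected biomarkers join six binary covariates: male sex and five
psychotropic ATC classes (antipsychotics, antidepressants, anxiolytics,
antiepileptics, hypnotics/sedatives). The split is stratified per class at
`⌈0.7·n⌉` — for class sizes 85/39/31/14 this is exactly 120 training and
49 test samples. Forests use 1000 trees and node size 1; mtry is tuned
over 1–20 by out-of-bag accuracy (the grid is published, the criterion is
not; OOB accuracy with ties to the smaller mtry is this package's choice).
Votes are tree fractions and sum to one. Importance is reported on four
indicators: the forest's OOB permutation importance, a held-out
permutation accuracy drop, mean Gini decrease, mean minimal depth (trees
not using a feature contribute depth + 1), and root-split counts. Test-set
metrics are computed once and never used for tuning. Missing values are
median-imputed with training-set medians.

## Monte-Carlo augmentation

The generator models each class's biomarkers as Gaussian on the logit
scale (fractions clamped to [1e-4, 1−1e-4]) with covariance shrunk toward
its diagonal, `(1−γ)S + γ·diag(S)`, taking the smallest γ on a 0.01 grid
with condition number ≤ 1e6; covariates are independent Bernoulli at the
observed class prevalences, and classes receive largest-remainder
allocations of the requested n (500 by default, proportional to class
sizes — whether the published 500 were drawn per class or overall is
unstated). The published description fixes only "structure and statistical
properties"; matching the first two moments plus correlation on the logit
scale is this package's interpretation. Fidelity is validated per class
and feature on mean shift (≤ 0.3 pooled SD), SD ratio (0.7–1.4) and
correlation deltas (≤ 0.25). No age model is fitted: age is a cohort
summary, never a model feature.

Two honest limitations surface in the default run. First, empirical
correlation matrices of small classes (the 14-sample schizoaffective
group) cannot be reproduced to ±0.25 — the estimate itself has sampling
noise near 0.3 — so correlation cells fail for small classes; the fidelity
report says so rather than hiding it. Second, near-zero editing fractions
observed at finite depth are quantized counts, and a logit-normal fit
systematically overstates their spread; the self-consistency suite
therefore operates in a moderate editing range (0.1–0.4) where the
generator's law is an accurate description.

## The synthetic-cohort generator

Editing proportions follow a logistic-normal model: site-level logit means
(defaults cycle over 3–35% editing within each gene), per-site logit SD
0.4, exchangeable within-gene correlation 0.3, class-specific logit shifts,
inverse-logit mapping, then beta-binomial observation noise (concentration
200) at the read depth — 10,000 reads per sample split evenly over the
eight amplicons. The per-site logit SD is a field this package adds: a
correlation structure alone does not determine marginal variances. Default
class effects reproduce the qualitative published structure — SZ and SA
share identical shifts on *KCNJ15*, *LYN* and *PRKCB* (so SZ vs SA is
truly null at the editing level), BD shifts on the seven genes other than
*PRKCB* — with magnitudes (0.5–0.6 logit units) chosen once as realistic
moderate effects; the study reports no per-site effect sizes, so these are
calibration choices, not published claims. Demographics use the published
per-class sizes, male fractions, treatment prevalences and age summaries
(reported as mean ± SD; the table caption's "SEM" label conflicts with the
column values and SD is used). Covariates are sampled independently given
class, because only marginal prevalences are published.

Read-level simulation assigns each read a whole phased editing pattern;
sites within a read are independent Bernoulli draws by default (a
comonotone option exists), with a symmetric 1e-3 sequencing error.

What passing tests show: the pipeline's operations are correct on data
satisfying their assumptions (logistic-normal proportions, independent
covariates, phased reads), calibrated under null labels, and powered under
planted effects. What they do not show: performance on real cohorts, whose
editing distributions, linkage between sites, batch structure and
covariate interactions the generator does not attempt to model. The
published clinical AUCs (0.91–1.0) are training-set values on a private
cohort and are not reproduced here; the default synthetic cohort yields
AUCs of 0.82–0.95, and notably its SZ|SA signature reaches ~0.95 despite a
null SZ–SA difference — a caution about full-sample mROC fitting with ~30
features and 45 samples.

## Problem sizes and determinism

Everything is seeded: the cohort is a pure function of its spec, pipeline
stages derive seeds from the global seed by fixed offsets, and rerunning
with the same configuration writes byte-identical TSVs. The test suite's
simulation sizes (null-calibration over 50 seeds at n = 120, planted
Boruta power over 20 seeds at n = 200/class, Gaussian mROC checks at
n = 20,000, importance structure over 10 seeds at n = 140–320/class) were
chosen to hold Monte-Carlo error comfortably below the asserted margins
while keeping the default suite around two minutes on one CPU.
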