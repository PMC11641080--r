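# editsig

Blood A-to-I RNA editing biomarker signatures for differentiating
psychiatric diagnoses.

## The problem

Bipolar disorder (BD), schizophrenia (SZ) and schizoaffective disorder (SA)
share overlapping mood and psychotic symptoms, and misdiagnosis delays
effective treatment by years. A-to-I RNA editing — enzymatic deamination of
adenosine to inosine, read as A→G mismatches in sequencing — is dysregulated
in psychiatric disease and measurable in blood. `editsig` implements a
complete analysis pipeline for targeted-amplicon editing data over an
eight-gene panel (*CAMK1D*, *GAB2*, *IFNAR1*, *KCNJ15*, *LYN*, *MDM2*,
*PDE8A*, *PRKCB*) in a four-group case–control design (healthy controls,
BD, SZ, SA):

1. **Editing quantification** from aligned reads (SAM) or nucleotide count
   tables: per-site editing fractions `G/(A+G)` (plus strand) or `C/(T+C)`
   (minus strand), per-read joint editing patterns (isoforms), motif
   aggregates, depth QC and background filtering.
2. **Feature selection**: adaptive differential testing (Shapiro–Wilk and
   variance gates choosing Mann–Whitney, Student's or Welch's *t*),
   Benjamini–Hochberg FDR, correlation pruning at |r| > 0.6, shadow-feature
   (Boruta-style) all-relevant selection, and mutual-information ranking.
3. **Target Editing Index (TEI)**: per gene, the Su–Liu AUC-maximizing
   linear combination of its selected editing variants,
   `a ∝ (S₀ + S₁)⁻¹ (μ₁ − μ₀)`, Box-Cox transformed toward normality, with
   pairwise group tests at FDR < 0.10.
4. **mROC virtual markers**: for each of the six diagnostic comparisons
   (CTRL|BD, CTRL|SZ+SA, BD|SZ+SA, CTRL|SZ, CTRL|SA, SZ|SA) the linear
   combination `Z = a·biomarker₁ + b·biomarker₂ + …` of globally normalized
   biomarkers maximizing the ROC area, reported with AUC, sensitivity,
   specificity, Youden cutoff, PPV and NPV.
5. **Integrated random forest**: the selected biomarkers plus sex and five
   psychotropic ATC treatment-class covariates in a multiclass random
   forest (1000 trees, node size 1, mtry tuned on 1–20 by out-of-bag
   accuracy, stratified 70/30 split), with vote probabilities and
   multi-indicator feature importance (permutation, impurity, minimal
   depth, times-a-root).
6. **Monte-Carlo augmentation**: a per-class logit-scale Gaussian generator
   with shrunk covariance, largest-remainder class allocation, fidelity
   validation against the original data, and prediction-error estimation
   on synthetic points.

Because the clinical cohort is available only on request, the package ships
a first-class **synthetic-cohort generator** whose defaults reproduce the
published study structure: class sizes 85/39/31/14, the per-class sex and
treatment prevalences, truncated-normal ages, and logistic-normal editing
proportions with beta-binomial read noise at a 10,000-read depth floor.
Every stage of the pipeline is tested against it.

## Worked example

```r
library(editsig)

res <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
res
#> <pipeline_result>
#>   samples: 169
#>   selected biomarkers: 27
#>   RF test accuracy: 0.857

res$selection
#> <feature_selection> 27 of 48 biomarkers selected

glance(res$signatures)[, 1:8]
#>   signature    comparison   auc    se    sp cutoff   ppv   npv
#> 1        Z1    CTRL vs BD 0.878 0.923 0.741  0.941 0.621 0.955
#> 2        Z2 CTRL vs SZ+SA 0.828 0.800 0.776 -2.299 0.655 0.880
#> 3        Z3   BD vs SZ+SA 0.879 0.711 0.974 -0.982 0.970 0.745
#> 4        Z4    CTRL vs SZ 0.824 0.806 0.741 -1.144 0.532 0.913
#> 5        Z5    CTRL vs SA 0.943 1.000 0.906 -1.148 0.636 1.000
#> 6        Z6      SZ vs SA 0.945 0.929 0.871 -1.768 0.765 0.964

res$rf$confusion
#>       predicted
#> truth  CTRL BD SZ SA
#>   CTRL   25  0  0  0
#>   BD      1 10  0  0
#>   SZ      2  0  7  0
#>   SA      0  0  4  0

head(tidy(res$rf), 3)[, 1:2]
#>   feature        permutation_importance
#> 1 antipsychotics                 0.0591
#> 2 antiepileptics                 0.0315
#> 3 LYN_s3                         0.0146
```

The pipeline simulates the study-sized cohort, selects 27 of 48 candidate
site biomarkers through the p-value → correlation → shadow-feature cascade,
fits the six virtual markers (AUCs 0.82–0.95 under the default synthetic
effect sizes), classifies the 49 held-out samples at 86% accuracy, and — as
in the clinical analysis this emulates — finds the antipsychotics flag the
most influential feature while sex contributes nothing. Every stage table
is also written as TSV when `outdir` is given, and `autoplot()` methods
exist for TEI results, signatures and RF reports.

Fitted objects follow broom conventions: `tidy()` returns coefficient or
importance tables, `glance()` one-row (or per-comparison) summaries.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/editsig run --seed 1 --outdir out/
Rscript inst/cli/editsig summary --cohort out/cohort.tsv
```

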