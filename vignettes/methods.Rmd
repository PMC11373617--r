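---
title: "Methods: multiomics prediction of whole-mount Gleason grade risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomics prediction of whole-mount Gleason grade risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gleasonomics)
```

## The prediction problem

In prostate cancer, the definitive grading of tumor aggressiveness — the
ISUP grade group derived from the whole resected prostate — is only known
after surgery. Needle-biopsy grading, the clinical standard available before
treatment decisions, disagrees with whole-mount grading in a substantial
fraction of patients. `gleasonomics` implements a multiomics machine-learning
pipeline that predicts the binary whole-mount risk group (high: ISUP ≥ 3;
low: ISUP < 3) from features available at biopsy time: clinical parameters,
PSMA-PET radiomics, pathway-level genomics from whole-exome sequencing,
immunohistochemistry (IHC) pathomics, and the biopsy-derived ISUP grade
itself (bxISUP).

The cut at grade 3 is used because grade groups 1–2 versus 3–5 give the
strongest prognostic stratification; the positive ("high") class drives all
sensitivity/PPV conventions in the package.

## Feature engineering

### Genomics: from variants to pathway disruption

Each somatic variant carries up to three pathogenicity scores: EVE and
PolyPhen on $[0,1]$ and CADD on an unbounded positive scale. The package
combines them into a per-variant *metascore*

$$M_v = \operatorname{mean}\{\text{EVE}_v,\ \widetilde{\text{CADD}}_v,\ \text{PolyPhen}_v\},$$

over the scores that are present, where $\widetilde{\text{CADD}}$ is CADD
min-max normalized over all variants of the cohort (`normalize_cadd()`). A
degenerate range (all CADD equal) maps to 0. Variants with no score at all
cannot enter disruption scores but still count toward mutational burden,
which is defined by variant counting alone.

Gene-level disruption is the sum of metascores of the patient's variants in
the gene, $D_g = \sum_{v \in g} M_v$, and pathway disruption sums member
genes, $D_p = \sum_{g \in p} D_g$ — a gene in several pathways contributes to
each. Two global features complete the block: tumor mutational burden
$\mathrm{TMB} = n_{\text{variants}} / (\text{sequenced bp} / 10^6)$ and CNV
burden $B$, the fraction of the sequenced territory covered by copy-number
segments. Segments are merged and intersected with the territory before
summation (interval arithmetic via `IRanges`), which guarantees $B \le 1$.
With the default 51-pathway catalog the genomics block has $51 + 2 = 53$
columns.

Open choices the upstream description leaves unstated — whether EVE/PolyPhen
are re-normalized, and whether the combination is a mean or a weighted sum —
are resolved as "use as-is" and "unweighted mean of available scores"; both
are the simplest readings and are isolated in `normalize_cadd()` /
`variant_metascore()` so alternative conventions are one-line changes.

### Radiomics: SUV metrics and an IBSI-convention texture subset

PET volumes are resampled to 2 mm isotropic spacing before extraction.
Resampling uses separable cubic interpolating splines per axis
(`stats::splinefun`, natural boundary); the mask is resampled
nearest-neighbor and re-binarized. On constant fields and linear ramps this
interpolation is exact, which is what the correctness tests assert.

From the resampled pair the package computes the six conventional SUV
metrics (SUVmin/max/mean, SUVpeak, PSMA-TV, TL-PSMA = SUVmean × PSMA-TV),
18 first-order histogram features and a 10-feature GLCM set. Intensities
are discretized with a fixed bin width of 0.3 SUV anchored at the in-mask
minimum, so bin labels are invariant to uniform uptake shifts. GLCM matrices
are accumulated at distance 1 over the 13 unique 3D directions, restricted
to in-mask voxel pairs, symmetrized, normalized, and features are averaged
over directions. SUVpeak is the best mean over a 1 ml sphere (PERCIST-style
radius ≈ 6.2 mm) with both the center and the averaged voxels restricted to
the mask, so every extracted value is invariant to voxel values outside the
VOI. Zero-variance VOIs report skewness/kurtosis 0 (with a warning) instead
of NaN so downstream tables stay numeric.

The full 100+-feature radiomics set of a dedicated IBSI extractor is out of
scope in-repo; `extract_radiomics()` exposes a delegation hook
(`extra_extractor`) behind the same `rad::<family>::<name>` column contract,
and the synthetic cohort emulates a precomputed 113-column radiomics-wide
table (107 texture/shape/histogram names + the 6 SUV metrics) so the design
matrix always carries the full schema.

### Pathomics: H-scores

For each IHC core the modified H-score is
$H = 1\cdot\%_{\text{weak}} + 2\cdot\%_{\text{moderate}} + 3\cdot\%_{\text{strong}} \in [0, 300]$;
the unstained remainder carries weight 0. Per patient and marker, tumor
cores (three per patient by design; normal cores are excluded) are
aggregated to an average and a maximum H-score. Missing cores shrink the
aggregate to the available ones; a patient-marker pair with no tumor core
becomes a missing feature and is handled by fold-wise imputation. With 11
markers this yields 22 columns; a 23rd column carries the TMA-core ISUP
grade (grade group of the highest-grade tumor core), configurable via
`tma_grade_column`.

### Assembly

`assemble()` inner-joins the blocks on patient id against the label table,
tags every column with one of five categories (clinical, radiomics,
genomics, pathomics, bxISUP) and never drops rows: a patient absent from a
block gets missing cells. The default schema is 13 + 113 + 53 + 23 + 1 = 203
features. The missingness filter drops columns whose missing fraction
*strictly* exceeds 30%; inside cross-validation it is re-applied per fold on
the training partition, the whole-table version exists for reporting.

## The evaluation engine

Evaluation uses 100-fold stratified Monte Carlo cross-validation: each fold
is an independent stratified 70/30 split (per-class training counts rounded
to nearest, the larger class absorbing the ±1 needed to hit the overall
rounded size; a 28/37 cohort gives 46 = 20 + 26 training patients). Within
every fold, in order and fitted on the training partition only:

1. missingness filter (> 30% missing among training rows);
2. k-nearest-neighbor imputation (k = 5), Euclidean distance over the
   dimensions observed in both rows, inverse-distance weights, exact matches
   dominating; because imputation precedes z-scoring, distances are computed
   on train-fitted min-max scaled copies and imputed values returned on the
   original scale;
3. z-scoring with train-fitted mean and population SD; zero-variance columns
   map to zeros;
4. mRMR feature ordering (MID criterion: greedy maximization of
   label-relevance minus mean redundancy, both as mutual information after
   equal-frequency discretization into min(5, ⌊n/5⌋) bins; features with at
   most that many distinct values keep their values as categories, since
   quantile breaks would merge a binary or sparse feature into one
   degenerate bin and zero out its information content; ties break by
   column order);
5. random search (20 draws by default) over the classifier family's
   documented space *and* the selected-feature count k ∈ {4, 6, 8, 10, 12,
   16}, scored by mean AUC over 3 inner stratified 75/25 shuffle splits;
6. the best configuration is refit on the full training fold; the isotonic
   calibration map is fitted on the winning configuration's held-out
   inner-split predictions, so it never sees in-sample scores. The
   calibration map carries an infinitesimal (< 1e-9) strictly increasing
   component so it is injective across flat isotonic steps — test-score
   ranks, and hence AUC, are exactly preserved;
7. calibrated scoring of the test partition and metric computation (AUC by
   midrank statistic; ACC/SNS/SPC/PPV/NPV at threshold 0.5 on calibrated
   probabilities).

Five classifier families are supported behind one interface: kNN
(`class::knn` vote fraction), random forest (`ranger`, probability
forests), gradient-boosted trees (`xgboost`), RBF SVM (`e1071`, decision
values oriented toward the high class) and elastic-net logistic regression
(`glmnet`). Random-search spaces: kNN k ∈ {3,…,11}; RF trees ∈
{100, 200, 300} (training folds have ~46 rows; forests plateau well below
that), mtry fraction U(0.2, 0.9), min node size {1, 3, 5}; XGB rounds
{25, 50, 100}, depth 2–5, η U(0.05, 0.4), subsample U(0.6, 1); SVM cost
2^U(−3,5), γ 2^U(−7,1); LGR α U(0, 1), λ 10^U(−4, 0).

Every stochastic step draws its seed from the master seed through a counter
stream (`derive_seed`), never from the data, so perturbing any held-out
value cannot change a fold's fitted transforms — the leakage sentinel in the
test suite asserts exactly this, and summaries are bit-reproducible per
seed. Per-metric summaries report the fold mean with percentile (2.5/97.5)
95% intervals. Fold failures are collected; a run aborts if more than 10%
of folds fail.

`baseline_single_feature()` evaluates bxISUP alone (raw grade as score,
clinical cut at grade ≥ 3) over the same folds — the clinical comparator.
`fit_final_model()` re-runs the pipeline once on the whole cohort with a
fixed selected-feature count (default 8) to produce the single model used
for patient-level explanation.

## Explainability

*Permutation importance* is the drop in test-partition AUC after permuting
one column, averaged over repeats; per-fold results are averaged over folds
(`importance_over_folds`), with features a model does not use contributing
exactly 0. `category_importance()` averages within the five category tags.

*Shapley values* are estimated by Monte Carlo permutation sampling against a
marginal background: for each sampled permutation and background row, each
feature's marginal contribution is the model-output change when that feature
switches from background to patient value. Contributions telescope, so
estimated values sum exactly to the patient's prediction minus the sampled
background mean.

*Surrogate trees* distill a reference model into a depth-limited CART tree
trained on the reference's predicted labels. Fidelity — how well the tree
reproduces the reference — is the AUC of the tree probability against the
reference predicted label on a held-out 30% split (`fidelity_auc`).
`fidelity_insample` reports the same quantity on the training rows: it
measures representational capacity and is nondecreasing in depth, whereas
held-out fidelity also carries generalization noise and need not be
monotone. The tree is rendered as an IF/THEN rule list — the simplified
diagnostic workflow.

## The synthetic cohort generator

All pipeline behavior is validated on generated cohorts that mirror the
study's data structure (`cohort_config()` defaults): 65 patients, 57%
high-risk prevalence, the 203-feature schema, ~35% missingness for
image-read clinical parameters, 3 tumor + 3 normal IHC cores per marker,
sparse somatic variant tables with Beta-distributed EVE/PolyPhen and
Gamma-distributed CADD scores, CNV segments over a 30 Mb sequenced
territory, and spherical-lesion SUV phantoms with Gaussian noise.

Labels are drawn first — ISUP grades from a categorical distribution whose
mass above the ≥ 3 cut equals the configured prevalence — and features are
generated conditional on the binary label. A feature with planted effect
$e$ therefore differs between classes by $e$ SD units in expectation, and a
feature with effect 0 is label-independent. bxISUP is derived through a
confusion kernel with configurable concordance (default 70%; discordant
draws move one grade). The IHC cores carry the biopsy-kernel grade, not the
whole-mount truth — the TMA punch mimics a targeted biopsy, and copying the
true patterns would leak the label into the pathomics block.

Three generator subtleties matter for interpretation:

* a *null* cohort requires `bx_informative = FALSE` (bxISUP drawn from the
  marginal grade distribution): a biopsy grade linked to the truth by any
  concordance kernel is itself a strong predictor, so "all effects zero"
  alone does not make the prediction problem null;
* IHC effects are planted at core level, so the avg and max H-scores of a
  marker move together; an *isolated* planted feature must be a directly
  drawn column (clinical or radiomics);
* pathway-level genomics signal cannot be planted as a mean shift (the
  scores are sums over generated variants); `pathway_rate_boost` multiplies
  the mutation rate of a pathway's genes in the high-risk class instead.

What the generator does *not* emulate: real radiomics inter-feature
correlation structure (the 113-column table is drawn independently per
column), realistic linkage between genomic lesions and expression, scanner
effects, or informative missingness. Passing the planted-signal and
null-calibration tests therefore demonstrates that the *pipeline* is
leakage-free and recovers known structure — not that any particular AUC is
attainable on real patients.

## Problem sizes and numerical choices

The acceptance tests run the full pipeline at the study scale (65 patients,
203 features, 100 folds; the null-calibration check repeats this over five
generator seeds), with unit tests on reduced cohorts (40 patients, reduced
schema). Monte Carlo Shapley audits use 64 coalition permutations per
patient on the 8-feature final model. Tolerances: oracle equivalences at
1e-12; interpolation identity at 1e-6; stochastic recovery checks use 3-SE
bands around their Monte Carlo targets. Degenerate inputs are handled
explicitly: empty VOIs, single-voxel GLCM, constant calibration scores,
zero-variance columns and all-missing variant score triples each have a
defined, warned behavior rather than an error deep in a fold.

## Known limitations

The radiomics subset covers first-order + GLCM + SUV metrics; other IBSI
texture families arrive only via the delegation hook. The kNN classifier
vote is unweighted. The 51-pathway catalog is an input, not curated content.
Reported confidence intervals are percentile intervals over Monte Carlo
folds and should not be read as inference about an external population.
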