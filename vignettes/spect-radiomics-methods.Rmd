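---
title: "Standardized SPECT radiomics for coronary calcium prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized SPECT radiomics for coronary calcium prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectRadiomics)
```

## The scientific problem

Myocardial perfusion stress SPECT (MPSS) images relative blood flow in the
left-ventricular myocardium. A clinically "normal" (non-ischemic) scan does
not rule out coronary atherosclerosis: a substantial fraction of such
patients carry a positive coronary artery calcification (CAC) burden, which
is ordinarily quantified from a separate CT by the Agatston method, per
artery (LAD, LCX, RCA) and in total. This package implements a pipeline
that asks whether mild regional heterogeneity in the counts of a normal
MPSS scan — quantified by standardized 3D radiomic features per cardiac
segment — carries information about the per-artery CAC score, alone or on
top of ten routine clinical covariates.

The pipeline has five stages, each a module of the package:

1. a synthetic cohort generator (`generateCohort()`), so everything
   downstream is testable without patient data;
2. feature extraction (`extractFeatureTable()`): a 487-descriptor
   standardized catalog, fixed-bin-number discretization, and from-scratch
   3D texture matrices;
3. a blind-to-outcome feature-selection cascade
   (`runSelectionPipeline()`);
4. univariate Spearman screening with Benjamini-Hochberg control
   (`spearmanScreen()`);
5. multivariate stepwise linear regression inside a nested resampling
   protocol, aggregated across repetitions by Fisher's method
   (`runExperiment()`, `buildResultsTable()`).

## Feature computation

### Discretization

Perfusion SPECT voxels are arbitrary-unit counts, so features are computed
on fixed-bin-number (FBN) discretized intensities: within an ROI,
`level(x) = ceiling(Ng * (x - min) / (max - min))` with `level(min) = 1`.
Every non-constant ROI then spans levels `1..Ng` exactly, which makes
subjects comparable but also forces four descriptors to be constant across
any cohort: histogram minimum (always 1), maximum (always `Ng`), range
(always `Ng - 1`), and the NGLDM dependence-count percentage (always 1,
since no neighbourhood cutoff is applied). The selection cascade removes
exactly these four on any cohort.

### The catalog and what is computed

The catalog (`buildCatalog()`) enumerates 487 descriptors: morphology (29),
local intensity (2), intensity statistics (18), intensity histogram (23),
intensity-volume histogram (7), GLCM (25 x 6 aggregations), GLRLM (16 x 6),
GLSZM/GLDZM (16 x 3 each), NGTDM (5 x 3), NGLDM (17 x 3). Because the
volumes are isotropic, all 2D/2.5D aggregations (272 descriptors) are
redundant and exist in the catalog only so the cascade can account for
them; morphology and local intensity are likewise catalog-only, since the
segments come from a template-like segmentation whose shape carries no
subject information and the intensities have no absolute calibration. The
remaining 184 descriptors are computed: statistics, histogram, IVH, 3D
GLCM/GLRLM in both averaged and merged aggregations, and the 3D zone and
neighbourhood families.

Texture conventions: 13 unique directions at Chebyshev distance 1 (GLCM
symmetrized; "averaged" = mean of per-direction feature values, "merged" =
features of the direction-summed matrix); zones by 26-connectivity; GLDZM
distance = minimal Chebyshev distance to a non-ROI voxel (boundary voxels
at distance 1, outside-grid counts as non-ROI); NGTDM/NGLDM use the
26-voxel neighbourhood, NGLDM with coarseness parameter 0; entropies in
bits (base-2 logs). Matrix dimensions (run length, zone size, distance,
dependence count) are sized to the observed maxima — only scalar features
leave the module. Undefined values (zero-variance correlation terms,
single-level neighbourhoods) are NaN sentinels, never dropped; a feature is
treated as constant only if its value — sentinel included — is identical
cohort-wide.

The IVH is computed on the discretized levels: the volume fraction
`nu(i) = P(level >= i)` over the level grid, intensity fractions
`gamma(i) = (i-1)/(Ng-1)`; V10/V90 read `nu` at the 10%/90% intensity
fractions, I10/I90 are the intensity fractions where at most 10%/90% of the
volume remains, and the seventh descriptor is the area under the `nu`
curve. The identity `sum_i nu(i) = E[level]` makes the IVH area a rescaled
histogram mean — one of several exact redundancies the cascade later
removes (see below).

### No resampling

Volumes are already isotropic; the pipeline performs no interpolation, no
gray-level rounding, and no re-segmentation.

## The selection cascade

Stages, in order, with their survivor counts (the first five are
structural and hold for any cohort):

| stage | rule | survivors |
|---|---|---|
| catalog | — | 487 |
| 1 | drop 2D/2.5D aggregations | 215 |
| 2 | drop intensity statistics, local intensity, morphology | 166 |
| 3 | drop features identical across subjects | 162 |
| 4 | drop the redundant GLCM/GLRLM 3D variety | 121 |
| 5 | drop one member of every Spearman-rho = 1 pair | data-dependent |
| 6 | drop dynamic range (variance/mean) below 1e-5 | data-dependent |
| 7 | recursive pruning at \|rho\| >= 0.95 | data-dependent |

The cascade never sees CAC scores; its interface takes feature values
only.

Design notes on the open points:

* **Stage-4 range comparison.** "Range" of a variety is the sum over its
  features of the per-feature range after rescaling both varieties to the
  union range of each feature pair, so that features on large scales do not
  dominate the comparison. Which variety loses is data-dependent; the two
  varieties correlate strongly on the diagonal (for run-length features
  essentially perfectly; for entropy-type co-occurrence features the
  correlation weakens on small cohorts).
* **Stage-5 identities.** Under the exact definitions, six GLSZM/GLDZM
  pairs coincide analytically — zone percentage, gray-level non-uniformity
  (raw and normalized), and additionally the low/high gray-level emphases
  and the gray-level variance, because all of these depend only on the
  gray-level marginal, which the two matrices share (identical zone
  decomposition). Further exact identities appear among co-occurrence
  features (sum average = 2 x joint average; dissimilarity = difference
  average; cluster tendency = sum variance), between the histogram mean and
  the IVH area, and between histogram uniformity/variance and their NGLDM
  counterparts (the NGLDM gray-level marginal counts every voxel). On
  thin-walled shells the GLDZM distance column can also degenerate to two
  values, rank-locking the small/large-distance emphases. All such pairs
  are detected and reduced to one member (the larger-range one kept); the
  per-stage report records every pair.
* **Stage-6 denominator.** Percent variance is `|variance / mean|`; for
  zero-mean features (|mean| < 1e-12) the variance itself is compared to
  the threshold.
* **Stage-7 determinism.** Features are sorted by their count of
  high-correlation partners; ties break by catalog order, making the
  recursion fully deterministic. Survivors are mutually below the
  threshold by construction, which the tests assert directly.
* **Pooling across segments.** Value stages operate on the subject x
  segment stacked matrix, so a single feature set emerges that is shared
  by all seven segments, mirroring the use of one selected set for every
  segment downstream.

### Gray-level selection

Candidate bin counts are compared on three diagnostics per GL computed on
the 166-feature tables: the number of identical features, the fraction
with low dynamic range, and the number of feature pairs with
\|rho\| >= 0.9. GLs dominated on all three are excluded; among the
non-dominated set the configured preference (default 64) is returned, with
ties between equally good levels resolved to the smaller count (coarser
discretizations are cheaper and at least as robust). Very coarse levels
(4-16 bins) cannot express heterogeneity; very fine ones (256-512) spread
a ~460-voxel segment over more bins than voxels, degenerating the
higher-order matrices — 64 sits in the stable middle, consistent with the
diagnostics.

## Univariate analysis

Per segment, each selected feature is Spearman-correlated with the CAC
score of the same artery (total CAC for the whole myocardium), in both a
continuous coding and a discrete coding by the clinical Berman strata
(0, (0,10], (10,100], (100,400], (400,1000], >1000 — six ordinals).
Two-sided p-values use the t approximation for n >= 10 and exact
permutation enumeration below that. Benjamini-Hochberg step-up flags are
attached at q = 0.05. On null cohorts (severity coupling off) the pass
fraction stays within the FDR budget, the property the tests check.

## Multivariate analysis

### Stepwise regression

Terms are blocks: one column per radiomic feature or continuous covariate,
whole dummy blocks for categorical covariates (gender, race, smoking and
the binary history variables), built against the full level set so
resampled subsets lacking a level remain estimable. The intercept is
immutable. A term enters when its partial-F p-value is at most `p_enter`
(default 0.05) and, under the default AIC criterion, the move lowers AIC;
among admissible additions the best criterion improvement wins. When
nothing can enter, the worst in-model term with partial-F p >= `p_remove`
(default 0.20) leaves. The default reconciles the two published
specifications of the procedure (F-test thresholds and an AIC step
criterion) by using the F-tests as gates and AIC as the ranking; a pure
p-value mode is available (`criterion = "pvalue"`).

Candidates enter in a data-driven order: features with training-set
Spearman p below 0.3 are kept, sorted by |rho| descending (ties by catalog
order). Multi-level categorical blocks, for which Spearman is undefined,
are ranked by a Kruskal-Wallis test with `sqrt(H/(n-1))` as the pseudo-rho
sort key.

### Resampling protocol

Per trial: 15% of subjects are held out as the test set; the remaining 85%
are split 75/25 into train/dev 20 times. The stepwise model is fit from
the intercept on train, then refit on dev *starting from the trained
model* (the dev refit uses the same gates). The best dev model by AIC is
selected — an intercept-only winner is skipped in favour of the best model
with more than one term; if no such model exists the trial is invalid and
redrawn with a fresh derived seed. The selected model's *terms* are refit
on the full 85% before predicting the test set (the published protocol
does not say which coefficients score the test set; refitting on all
non-test data is the standard choice and uses the most data without
touching the test set). Test performance is the Pearson correlation
between predicted and observed scores, with its two-sided p-value.

The whole operation repeats 50 times with fresh shuffles; the 50 test
p-values combine by Fisher's method, `X = -2 * sum(ln p_i)`, referred to a
chi-squared distribution with 100 degrees of freedom (critical value
135.81 at alpha = 0.01). The three configurations — radiomics-only,
clinical-only, combined — run per segment, giving a 3 x 7 table of X
statistics.

Two published statements conflict on which inner model to carry forward
("highest AIC" vs best log-likelihood); AIC semantics make the lowest-AIC
model the coherent reading, which is the default, with
`select = "loglik"` available. The CAC outcome is modeled untransformed by
default (`log1p_outcome` switches a log1p transform on); the whole-
myocardium segment is paired with total CAC.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes; it
is not a physics simulation.

* **Geometry.** A half-ellipsoid left-ventricle shell on a 64^3 grid of
  4.8 mm isotropic voxels (outer semi-axes 42/42/72 mm, wall 15 mm),
  jittered per subject in overall scale (sd 6%) and wedge orientation
  (sd 8 degrees). Three angular wedges (LAD 150 degrees, LCX and RCA 105
  degrees each, apex assigned to LAD) partition the shell into the
  "17-style" artery groupings; the "MIM-style" tight wedges trim 14
  degrees at each boundary and exclude basal and apex-tip bands. At these
  defaults the tight LAD wedge averages about 460 voxels, matching the
  segment size the gray-level analysis reasons about.
* **Intensities.** `base_counts` (100) x a smooth multiplicative Gaussian
  random field (correlation length 12 mm, relative sd 0.25) x (1 -
  severity-driven suppression), plus Gaussian noise with variance equal to
  the mean — a Poisson surrogate that keeps intensities continuous, which
  is adequate because only ranks and discretized levels matter downstream.
  An apical-thinning artifact (probability 0.3, 35% suppression of the
  apical band) emulates the well-known reconstruction artifact.
* **Severity coupling.** Each artery carries a latent gamma-distributed
  severity, scaled up with a fixed clinical risk index (age, diabetes,
  hypertension, hyperlipidemia, smoking, family history, gender). Severity
  suppresses uptake in the artery's territory (strength `severity_effect`)
  *and* drives the CAC hurdle, so image texture and calcium share a common
  cause. `severity_effect = 0` is the null model: texture independent of
  CAC given the covariates; type-I-error tests rely on it.
* **Clinical covariates.** Categorical marginals default to the reference
  cohort's frequencies (smoking 47.7/29.7/22.6%, diabetes 32.1%,
  hypertension 70.1%, hyperlipidemia 47.3%, family history 38.6%, the
  seven-level race distribution, and a near-even gender split). Age, BMI
  and LVEF are truncated normals — age 62 +/- 12 on [25, 90] years, BMI
  29.5 +/- 6 on [15, 55], LVEF 60 +/- 8 on [20, 85]% (the published LVEF
  histogram is not numerically recoverable; a truncated normal around the
  normal-scan range is the natural choice).
* **CAC scores.** Per artery, a hurdle model: P(score > 0) is logistic in
  the clinical index and the latent severity (intercept -1.9, calibrated
  once by simulation so ~58.4% of subjects have non-zero total CAC);
  positive scores are lognormal (log-mean 4.0 + 0.4 x severity, log-sd
  1.8), spreading realistically across the Berman strata. Total CAC is the
  sum over LAD + LCX + RCA; no left-main score is generated since no
  left-main segment is analyzed.

What the generator does **not** emulate: collimator blur, attenuation and
reconstruction correlations, anatomically exact 17-segment polar geometry,
inter-feature dependence structures of real myocardium, or the heavy
right tail of extreme calcification. Passing tests therefore demonstrate
the *machinery* — calibration, blindness, error control, power ordering —
on data with the assumed statistical structure, not clinical performance.

## Problem sizes and numerical choices

The test suite exercises the pipeline at desk scale, chosen to keep each
statistical check's Monte-Carlo error well inside its assertion margin:
cohorts of 30 subjects (45 for the end-to-end pipeline run, which also
reduces the resampling protocol to 4 x 3 repetitions), 5000 draws for the
hurdle calibration, 100+ random ROIs up to 6^3 against brute-force oracles,
10^4 replicates for the Benjamini-Hochberg null, and 6-8 replicates of the
full 50 x 20 protocol for the type-I check (at alpha = 0.01, two or more
rejections among eight nulls has probability below 0.3%). Gray-level
comparisons run on {4, 64, 512}, spanning the coarse, working and
over-fine regimes.

Numerical conventions worth knowing: population (1/N) moments throughout
the feature definitions; quantiles by R's default type-7 rule; histogram
mode ties resolve to the lowest level; rho = 1 detection tolerates 1e-12
in rank correlation; the stage-6 zero-mean guard at 1e-12; QR rank
detection drops rank-deficient candidates during stepwise moves; p = 0
inputs to Fisher's method clamp to the smallest positive double with a
warning. All randomness flows from explicit seeds (cohort seed; a master
stepwise seed spawning per-trial seeds), and the RNG state of the caller
is never disturbed.

## Known limitations

* The avg/merged diagonal correlation for entropy-type GLCM features is
  well below 0.98 on small synthetic cohorts, so stage 4's choice of which
  variety to drop can differ from run to run; the selection report records
  it.
* More rho = 1 identity pairs exist than the three zone-family twins
  (see the stage-5 note above); downstream counts after stage 5 are
  correspondingly smaller.
* The stepwise F-gates and the AIC criterion disagree in a narrow band of
  partial-F p-values (roughly 0.05-0.16 for single-column terms); the
  default resolves the band conservatively (both must agree for a move).
* Exact permutation p-values for Spearman below n = 10 enumerate all n!
  permutations; n = 9 is the practical ceiling.
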