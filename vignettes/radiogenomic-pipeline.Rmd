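---
title: "Radiomic surrogates of tumor hypoxia: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic surrogates of tumor hypoxia: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypoxrad)
```

`hypoxrad` links two readouts of the same tumor biology: texture on routine
MRI and a transcriptomic hypoxia score. This vignette documents the models
the package implements, the parameters that matter, what the synthetic
cohort does and does not emulate, and the design decisions taken where the
methodology left genuine freedom.

## The pipeline

A study consists of three co-registered volumes (Gd-T1w, T2w, FLAIR) and an
expert label map with three tumor compartments: necrotic core (label 1),
enhancing tumor (2), and edema including nonenhancing tumor (3). The
pipeline has five stages:

1. **Preprocessing** — resampling to a common grid (0.5 × 0.5 mm in plane,
   3 mm slices) and histogram-landmark intensity standardization.
2. **Texture extraction** — 30 per-pixel descriptors per
   protocol × compartment: 5 Laws energies, 12 Gabor magnitudes, 13 Haralick
   GLCM statistics; pooled across slices and summarised by the median;
   270 features per study.
3. **Hypoxia enrichment score (HES)** — single-sample gene-set enrichment of
   a 21-gene hypoxia signature on z-scored expression, clustered into
   ordered low/mid/high groups.
4. **Radiogenomic selection** — mutual information between each feature and
   the HES cluster label inside 50 × 3-fold stratified cross-validation;
   the 8 features most frequently in the per-run top 8 are retained.
5. **Survival analysis** — random-forest classification of survival-group
   pairs from the retained features, evaluated with Kaplan–Meier/log-rank,
   Cox hazard ratios and Harrell's concordance.

## Texture models and their numerical choices

**Laws energies.** The five 5×5 kernels are the symmetric self-products
L5L5, E5E5, S5S5, W5W5, R5R5 of the classical 1D vectors
(L5 = [1,4,6,4,1], E5 = [−1,−2,0,2,1], S5 = [−1,0,2,0,−1],
W5 = [−1,2,0,−2,1], R5 = [1,−4,6,−4,1]). Energy is the absolute filter
response; borders use half-sample reflection. Self-products are used because
a five-descriptor bank built from cross-products would be arbitrary, while
the self-products span level, edge, spot, wave and ripple symmetrically; all
but L5L5 are zero-sum, so they are invariant to intensity offsets.

**Gabor bank.** Each filter is a complex sinusoid under an isotropic
Gaussian envelope, applied separably. Frequencies f ∈ {0, 4, 16} are read as
cycles per filter window (window 15 px, envelope σ = window/6), the most
natural unit when only bare numbers are given; orientations
θ ∈ {45°, 90°, 135°, 180°} are the carrier wave-vector directions. f = 0
degenerates to the Gaussian envelope and is orientation-free; it is still
emitted once per orientation so the bank always has 12 stable names —
a deliberate naming-stability choice, the four maps are identical.

**Haralick statistics.** Per pixel, the GLCM of its 11×11 window is
accumulated over the four distance-1 offsets (0°, 45°, 90°, 135°),
symmetrized, and normalized; gray levels are min–max quantized to 64 levels
within the compartment's full 3D region so that all slices share one level
scale and features are invariant to intensity offset and scale. The 13
statistics are energy, contrast, correlation, sum-of-squares variance,
inverse difference moment, sum average, sum variance, sum entropy, entropy,
difference variance, difference entropy, and the two information measures of
correlation. Conventions for the historically ambiguous cases: sum variance
is the variance of p_{x+y} about the sum average; difference variance is the
variance of p_{x−y} about its own mean; correlation and IMC1 are defined as
0 when their denominators vanish (constant windows); IMC2's radicand is
clamped at 0. Pixels whose window yields no valid pair are treated as
missing and excluded from the median; a compartment absent from a study
yields missing features, imputed with training-split medians before
selection.

Window size, level count and offset distance are not dictated by the
methodology being reproduced; the defaults above are common radiomics
practice and are exposed in `glcm_params()`.

**Aggregation.** The median is taken over the pooled per-pixel responses of
all slices (not a median of per-slice medians): the region of interest is a
single 3D object and pooling weights every pixel equally.

## Intensity standardization

MR intensities carry no tissue-specific numeric meaning across scanners, so
texture computed on raw intensities would mix scanner effects with biology.
The landmark method learns, per protocol, the mean foreground percentile
landmarks (deciles plus the 1st/99th tails) mapped affinely to a fixed
[0, 4095] scale, and transforms each volume piecewise-linearly through its
own landmarks. Landmarks are order statistics (type-1 quantiles), which
makes the transform exactly invariant to affine intensity changes and
exactly idempotent — properties the test suite asserts at 1e-6. Foreground
is the union of the three compartments when a label map exists, otherwise an
Otsu threshold. Bias-field correction and registration are upstream concerns
of external tools; the synthetic cohort is generated aligned and bias-free.

## The hypoxia enrichment score

Expression is z-scored per gene across samples using the sample (n−1)
standard deviation; zero-variance genes are dropped with a warning. For one
sample the genes are ranked by descending z-score (ties broken by symbol for
determinism) and the enrichment statistic is the running sum
ES = Σᵢ (P_hit(i) − P_miss(i)), where P_hit steps by the normalized rank
weight |z|^α of in-set genes and P_miss steps uniformly over out-of-set
genes. The running-sum (rather than maximum-deviation) form is the
single-sample convention; α defaults to its canonical 0.25 and is exposed.
At α = 0 the score is a pure rank statistic: invariant under monotone
transforms and antisymmetric under rank reversal, both covered by tests.

The packaged signature (`inst/extdata/hypoxia_genes.gmt`) is a
package-curated, representative 21-gene set of HIF-pathway targets
(including VEGFA, ANGPTL4 and LGALS3); any GMT with the user's preferred
signature can be substituted. Group assignment clusters the 1D HES vector
(hierarchical, Euclidean, average linkage, cut at k = 3) and relabels
clusters low/mid/high by ascending mean; the final assignment uses the
interval boundaries between the ordered clusters, so groups are always
contiguous in HES. Clustering in the 21-gene space instead of on the 1D
score is a defensible alternative reading; the 1D choice is used because the
grouping consumed downstream is one-dimensional, and cluster cut-points are
always recomputed from the data, never hard-coded.

## Selection and survival

Mutual information is estimated by the plug-in formula on a contingency
table of quantile-binned feature values (4 bins) against the three HES
cluster labels — against labels rather than the continuous score because
continuous–continuous MI needs a density estimator the methodology does not
specify, and the downstream grouping is 3-way anyway. A feature "occurs" in
a CV run when it ranks in the per-run top 8 (the retained-subset size; the
occurrence cutoff is exposed as `per_run_k`). Ties are broken by fixed
column order, then mean rank, then name — every ordering in the package is
deterministic.

The survival classifier is a 50-tree Gini random forest. Training
predictions are aggregated per patient by majority vote over all CV runs in
which the patient was a test sample (ties: higher mean predicted
probability, then the worse-prognosis label); the held-out validation split
is predicted by a single forest retrained on the full training split.
Kaplan–Meier groups on both cohorts are the *predicted* labels — the
question is whether classifier-driven stratification separates survival.
Cox models use Efron tie handling and 95% intervals; the multivariate
radiomic row reports the min–max range of per-feature hazard ratios.
Harrell's C counts risk ties as one half and is checked against an O(n²)
brute-force pair count.

## What the synthetic cohort emulates

Each phantom study contains three nested ellipsoids (randomized centres,
semi-axes and eccentricities) whose per-protocol mean intensities follow the
expected contrasts (necrosis hypointense on Gd-T1w, edema hyperintense on
FLAIR). Intra-compartment texture is Gaussian-filtered white noise; in the
enhancing and edema compartments its amplitude grows and its correlation
length shrinks with the latent hypoxia level h ~ U(0, 1):

* amplitude sd(h) = 6 (1 + 2h) intensity units — raw-intensity variance
  increases with h;
* correlation length σ(h) = 3.2 − 2.6 h px — texture roughens with h, which
  is what amplitude-invariant (min–max quantized) GLCM statistics can see;
* scanner noise is i.i.d. Gaussian, sd 1.5.

Both texture laws are monotone in h by construction; the directions were
chosen so that each feature family has a planted signal to find: Laws/Gabor
energies read the amplitude, Haralick statistics the roughness. The necrosis
compartment keeps fixed texture parameters, giving the selection stage a
genuine planted/non-planted contrast. These constants were set while
constructing the generator so that the planted links are strong enough to be
recovered (e.g. enhancing-compartment entropy tracks h); they are generator
design choices, documented here once, not tuning knobs.

Expression profiles put the 21 signature genes at Normal(μ₀ + 3σ·h, σ)
against 200 null background genes — a deliberately strong 3σ planted shift.
Survival is Weibull with shape 1.8 and scale 40·e^(−1.8h) months, plus
independent uniform censoring at rate 0.1 and a small age effect (0.15 per
SD of age) so clinical covariates carry independent signal. The Weibull
constants were calibrated jointly by grid search against the cohort
statistics the generator is designed to emulate — survival-group proportions
of roughly 29/36/36% at the 7/16-month cuts and group mean survivals of
about 4, 11.5 and 29 months — which this parameterization reproduces to
within a few percent. The calibration targets are printed cohort statistics,
fixed before any acceptance measurement.

What the phantoms do **not** emulate: MR physics (no k-space, partial
volume, or bias fields), brain anatomy or skull, DICOM metadata, multifocal
tumors, or registration error (volumes are generated aligned). Passing
recovery tests therefore demonstrates that the pipeline's machinery recovers
a planted hypoxia–texture–survival chain; it does not certify performance on
real, messier data.

## Determinism and problem sizes

Every stochastic component is seed-driven: each study derives a private
stream from (master seed, study index), so any study can be regenerated
independently of cohort order; the CV plan, forests and acceptance script
all take explicit seeds, and an identical configuration reproduces every
report number bit for bit (asserted by a pipeline test).

The test suite exercises full resolution (96 × 96 × 24 voxels, 115 studies)
once — feature census, runtime and end-to-end recovery — and runs its
ten-replicate recovery loop at 40 × 40 × 10 voxels with the full 115-study
cohort shape, a size chosen to keep the suite fast; `scripts/acceptance.R`
runs its main pipeline section at full resolution. Across the replicate
loop, feature selection recovers planted-informative features and the HES
recovers the latent hypoxia level in every replicate; the validation
STS-vs-LTS log-rank on the predicted groups, however, is a small-sample test
(about 21 patients), and with survival drawn from a realistically noisy
Weibull law its significance replicates in most but not all seeds — an
inherent property of cohorts of this size rather than of the pipeline.

## Known limitations

* 2D texture operators on axial slices (no 3D GLCM), matching the
  slice-wise methodology; anisotropic voxels make this the natural choice.
* The exact landmark configuration of the cited standardization method, the
  GLCM window/level/offset constants, and the Gabor frequency unit are not
  uniquely determined by the methodology; the package's choices are
  documented above and exposed as parameters.
* The hypoxia signature is representative, not a canonical published list;
  swap in your own GMT for real analyses.
* Survival-group assignment uses observed (possibly censored) time, which
  slightly inflates the short-term group at the 10% default censoring rate.
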