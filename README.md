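# hypoxrad

Radiomic surrogates of tumor hypoxia and overall survival in glioblastoma.

Glioblastoma (GBM) is an aggressive brain tumor whose hypoxic
micro-environment drives treatment resistance and poor prognosis, but hypoxia
can currently only be measured invasively or with specialised imaging.
`hypoxrad` implements a radiogenomic pipeline that asks whether routine MRI
already carries that information: it extracts compartment-specific texture
descriptors from standard Gd-T1w, T2w and FLAIR scans, summarises the
transcriptomic hypoxia state of each tumor in a single-sample enrichment
score, links the two by mutual-information feature selection under repeated
cross-validation, and evaluates the selected radiomic markers as predictors
of short- (OS ≤ 7 months), mid- (7–16) and long-term (> 16) survival.

Because the archival image and expression data such an analysis needs cannot
be redistributed, the package ships a first-class synthetic cohort generator:
multi-contrast tumor phantoms with necrotic core, enhancing rim and edema
halo, expression profiles, clinical covariates and survival outcomes, all
driven by a latent hypoxia level `h` so that every downstream stage can be
validated against known ground truth.

## Methods at a glance

* **Texture features.** For every protocol × compartment, 30 per-pixel maps:
  5 Laws energies (the symmetric self-products `L5L5 … R5R5` of the 1D
  level/edge/spot/wave/ripple vectors), 12 Gabor magnitudes (frequencies
  f ∈ {0, 4, 16} cycles/window × orientations θ ∈ {45°, 90°, 135°, 180°}),
  and the 13 classical Haralick statistics of the local symmetrized
  gray-level co-occurrence matrix (64 levels, 11×11 window, four distance-1
  offsets). Per-pixel responses are pooled over all slices of the region of
  interest and summarised by the median → 3 × 3 × 30 = 270 features per
  study. The per-pixel GLCM engine is compiled (Rcpp).
* **Hypoxia enrichment score (HES).** Expression is z-scored per gene;
  each sample is scored with a single-sample gene-set enrichment statistic —
  the running sum ES = Σᵢ (P_hit(i) − P_miss(i)) over the ranked gene list,
  with rank weight |z|^α (α = 0.25) — against a packaged 21-gene hypoxia
  signature (VEGFA, ANGPTL4, LGALS3, CA9, SLC2A1, …). Scores are clustered
  (Euclidean, average linkage) into ordered `low`/`mid`/`high` groups.
* **Radiogenomic selection.** 50 iterations of stratified 3-fold
  cross-validation (150 train/test sets); per run, features are ranked by
  the plug-in mutual information MI = Σ p(x,y) log p(x,y)/(p(x)p(y))
  between quantile-binned feature values and the HES cluster label; the
  8 features with the highest top-k occurrence frequency across the 150
  runs are retained.
* **Survival analysis.** A 50-tree Gini random forest classifies each
  survival-group pair (STS/LTS, STS/MTS, MTS/LTS) from the 8 retained
  features under the same CV plan; groups are compared with Kaplan–Meier
  curves and the log-rank test, and Cox proportional-hazards models
  (Efron ties) report hazard ratios and Harrell's concordance index for
  clinical, radiomic and combined covariates.

## Worked example

```r
library(hypoxrad)

cfg    <- cohort_config(n_studies = 12, n_train = 8,
                        volume_shape = c(48, 48, 12), seed = 7)
cohort <- generate_cohort(cfg)

features <- extract_cohort_features(cohort)
features[1:3, c("patient_id", "split",
                "GdT1w__enhancing__laws__E5E5",
                "GdT1w__enhancing__haralick__entropy")]
#> # A tibble: 3 x 4
#>   patient_id split GdT1w__enhancing__laws__E5E5 GdT1w__enhancing__haralick__en…
#> 1 SYN-001    train                        7292.                            5.33
#> 2 SYN-002    train                        7463.                            5.03
#> 3 SYN-003    train                        5327.                            5.18

hes <- cluster_hes(score_cohort(cohort$expression))
head(hes, 4)
#> # A tibble: 4 x 3
#>   sample     hes cluster
#> 1 SYN-001  82.7  high
#> 2 SYN-002  -8.31 mid
#> 3 SYN-003 -45.7  low
#> 4 SYN-004 -43.6  low

cor(hes$hes, cohort$clinical$latent_h, method = "spearman")
#> [1] 0.902
```

The texture medians and the enrichment score are both readouts of the same
latent hypoxia level: studies whose enhancing rim is rougher (higher Haralick
entropy) score higher on the 21-gene signature, and the Spearman correlation
of 0.9 shows the score recovering the planted hypoxia gradient. The
end-to-end driver

```r
pipe <- run_pipeline(cohort_config(seed = 1))
print(pipe)
```

generates the default 115-study cohort (85 train / 30 validation,
96×96×24-voxel phantoms), extracts all 270 features, selects the 8
HES-linked features and prints the survival report (log-rank p per group
pair and cohort, hazard-ratio table with concordance indices).

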