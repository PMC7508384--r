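# vesselmorph

Outline-based analysis of vessel morphogenesis: how the shape of a
wheel-thrown clay body develops, gesture by gesture, from the pre-formed
lump to the final vessel — and whether different individuals follow
different routes to the same standardized form.

The package is aimed at motor-behaviour researchers and
ethnoarchaeologists working with staged 2D outlines of axisymmetric
objects (digitized right-half cross-section profiles per fashioning
gesture). It implements the full analysis chain:

1. **Outline processing** — pixel calibration, resampling to 256 points
   at regular heights, zero-phase Butterworth smoothing, mirroring into
   closed full outlines (`calibrate`, `resample_profile`,
   `smooth_profile`, `mirror_to_outline`).
2. **Size** — height, maximal diameter and exterior surface area
   (lateral surface of revolution, the overall size measure), per-potter
   coefficients of variation, 20-bin normalized time, and
   maximum-likelihood growth-curve models
   ESA ~ poly(bin, 3) with per-potter random intercepts/slopes compared
   by likelihood-ratio tests (`size_metrics`, `assign_time_bins`,
   `fit_growth_model`, `likelihood_ratio_test`).
3. **Shape** — elliptical Fourier analysis of closed outlines
   (Kuhl–Giardina coefficients (a_n, b_n, c_n, d_n) of the arc-length
   parametrized contour), size normalization by the first-harmonic
   semi-major axis, PCA shape space, per-trial trajectories, and
   Euclidean distances from group mean shapes at the pre-formed and
   final stages (`efa_coefficients`, `normalize_size`,
   `fit_shape_space`, `stage_distances`).
4. **Inference** — distance-based permutation tests (pseudo-F, among-
   potter R², exact enumeration on small designs), the Stage linear
   mixed model with per-potter random intercept and heteroscedastic
   per-potter residuals, Community × Trial repeated-measures ANOVA with
   generalized eta-squared, one-way ANOVA reconstruction from published
   means/CVs, and Pearson correlations with Fisher-z intervals
   (`permanova`, `stage_lmm`, `community_anova`,
   `oneway_anova_from_summary`, `pearson_ci`).
5. **Synthetic studies** — a generator of staged vessel-profile datasets
   with individual-specific pre-forms and routes converging on a shared
   final form with small individual signatures
   (`simulate_study`, `default_study_config`), used throughout the test
   suite and usable for power studies.

`run_pipeline()` composes all of it and returns (optionally writes) a
structured report; `write_study`/`read_outlines` define the CSV + JSON
interchange format for staged outline data.

## The core statistic

For trials grouped by potter, squared pairwise Euclidean distances
d²_ij between size-normalized coefficient vectors are partitioned as

    SS_total = (1/N) Σ_{i<j} d²_ij
    SS_within = Σ_g (1/n_g) Σ_{i<j ∈ g} d²_ij
    pseudo-F = (SS_among / (a−1)) / (SS_within / (N−a)),
    R² = SS_among / SS_total

with p-values from permuting potter labels. Run at the pre-formed and
final stages, R² measures how much of the shape variation is
among-potter: routes are idiosyncratic if R² is high early and drops as
the common final form is approached, with the contraction confirmed by
the Stage mixed model on shape-space distances.

## Worked example

```r
library(vesselmorph)

report <- run_pipeline(default_study_config(seed = 1),
                       n_points = 128, n_harmonics = 15,
                       n_permutations = 999)
report
#> analysis_report
#>   35 trials; PC1-3 variance: 71.7%, 18.6%, 7.3%
#>   permanova money_bank.pre_formed.pooled     R2 = 0.960, p = 0.001
#>   permanova money_bank.pre_formed.workshop1  R2 = 0.963, p = 0.001
#>   permanova money_bank.pre_formed.workshop2  R2 = 0.927, p = 0.001
#>   permanova money_bank.final.pooled          R2 = 0.328, p = 0.031
#>   permanova money_bank.final.workshop1       R2 = 0.341, p = 0.055
#>   permanova money_bank.final.workshop2       R2 = 0.170, p = 0.296
#>   stage LMM money_bank.pooled                F(1,62) = 367.5, p = 0
#>   stage LMM money_bank.per_community         F(1,62) = 286.7, p = 0
```

Seven simulated potters (two workshops) throw five money-bank-like
vessels each. At the pre-formed stage 96% of shape variation lies among
potters (each starts from an idiosyncratic pre-form); at the final stage
the among-potter fraction collapses to 33% as all converge on the shared
type form, and the Stage mixed model confirms that per-trial distances
from the group mean shape contract (F(1,62) = 367.5). The first three
principal components carry over 97% of shape variance, so trajectories
live comfortably in a 3D shape space.

Summary-table reconstructions work directly from published per-potter
means and CVs:

```r
tab <- final_dimension_summary("money_bank")
esa <- tab[tab$metric == "esa_cm2", ]
oneway_anova_from_summary(esa$mean, esa$cv_pct, n_per_group = 5)
#> ANOVA: F(6,28) = 64.28, p = 4.459e-15, generalized eta-squared = 0.932
```

## Vignette

`vignettes/vessel-morphogenesis.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the
package's numerical conventions.
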