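---
title: "Quantifying vessel morphogenesis from staged outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vessel morphogenesis from staged outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The problem

When an expert potter throws a vessel on the wheel, every manual
fashioning gesture deforms the clay body and leaves an observable trace:
the outline of the clay at that instant. The sequence of outlines from
the pre-formed lump (end of centring and opening, t = 0) to the final
vessel is the vessel's *morphogenesis*. Comparing morphogenetic routes
across individuals asks a motor-skill question with archaeological
stakes: do craftspeople in a common tradition reach the same
standardized final form by the same route (as high-fidelity copying of a
cultural model would predict), or does each expert follow an
idiosyncratic route that converges only at the end?

The quantitative core is a comparison of among-individual versus
within-individual shape variation at the earliest and final stages of
the process. `vesselmorph` implements the full chain: outline
processing, elliptical Fourier shape description, a PCA shape space with
per-trial trajectories, distance-based permutation tests, growth-curve
mixed models for size, and a heteroscedastic mixed model for shape-space
convergence — plus a synthetic-data generator that produces staged
studies with exactly this structure, so every stage of the pipeline is
testable without the original video recordings.

## Data model and outline processing

A **profile** is the right half of an axisymmetric object's
cross-section: ordered points (x >= 0 radial cm, y vertical cm) from
base to rim. Raw digitized profiles in pixels are converted with
per-axis calibration factors (`calibrate()`); per-axis factors cover
anisotropic video pixels and reduce to a single scalar when equal.

Profiles are resampled to 256 points at regular height intervals
(`resample_profile()`, linear interpolation, endpoints exact) and
optionally smoothed with a zero-phase 2nd-order Butterworth low-pass
filter (`smooth_profile()`). Zero phase matters: a causal filter would
shift the wall and bias diameters. The default cutoff is 0.15 of the
spatial Nyquist frequency; the source study names neither filter type
nor cutoff, so this is a package default, and results that depend on
fine outline texture are mildly sensitive to it. The filter removes the
endpoint-to-endpoint linear trend before filtering and restores it
after, with odd-reflection padding, so constant and conical walls pass
through unchanged and endpoint radii are preserved.

`mirror_to_outline()` exploits axisymmetry: the left edge is the right
edge with x negated. The closed contour is traversed counterclockwise
(right edge base to rim, a straight chord across the rim, the mirrored
left edge, a chord across the base). Straight chords are the minimal
closure assumption for an open clay surface; on-axis endpoints produce a
single smooth curve with no chords. The traversal convention is fixed so
Fourier coefficients are comparable across runs.

## Size: metrics, time bins, growth curves

`size_metrics()` returns height, maximal diameter and exterior surface
area (ESA). ESA — the overall size measure — is the lateral area of the
surface of revolution, summed as frustum areas
pi (x_i + x_{i+1}) slant_i; the base and rim discs are excluded (the
lateral sum is the standard estimator and is insensitive to whether the
top is open). At 256 points the discretization error on smooth profiles
is well below 0.1%.

Each trial's stage times are mapped to 20 equally spaced bins between
the first and last gesture (`assign_time_bins()`; left-closed intervals,
last stage clamped into bin 20). `fit_growth_model()` models ESA against
a third-order orthogonal polynomial of bin (built by `stats::poly`,
i.e. Gram-Schmidt on the observed bins), by maximum likelihood, with
optional per-potter random intercept, random slopes on the three time
terms (unstructured 4x4 covariance, hence 9 extra parameters), and
community fixed effects (main effect + 3 interactions, 4 parameters).
`likelihood_ratio_test()` compares nested fits by the change in
deviance. The intercept test has 1 df; note the chi-square(1) reference
is conservative for a variance component on the boundary, which the
test suite verifies empirically.

## Shape: elliptical Fourier analysis and the shape space

`efa_coefficients()` computes Kuhl-Giardina elliptical Fourier
coefficients of the closed outline under cumulative arc-length
parametrization, evaluated in closed form from the chain of segment
increments (exact for a polygon). No rotation or start-point
normalization is applied: all outlines share the vessel frame (axis at
x = 0, y up, start at the base on the right edge), so only size must be
corrected. `normalize_size()` divides all coefficients by the
semi-major axis of the first-harmonic ellipse (the largest singular
value of the 2x2 first-harmonic matrix) and zeroes the bias terms,
giving exactly scale-invariant shape descriptors. The literature also
uses |a1| as the size measure; that variant is available via
`method = "a1"`. The default of 20 harmonics retains > 99.9% of
harmonic power on simulated vessel outlines.

Two numerical caveats are worth stating because they are intrinsic to
arc-length parametrization, not implementation defects: an eccentric
ellipse is *not* a one-harmonic shape in arc length (its even harmonics
vanish by symmetry, but odd harmonics above 1 do not), and
re-analysing a reconstructed contour reproduces the coefficients
exactly only for constant-speed contours such as circles; for vessel
outlines the round trip drifts by well under 1%.

`fit_shape_space()` performs centered PCA (covariance matrix — the
coefficients share units after normalization) via spectral
decomposition, with a deterministic sign convention (largest-magnitude
loading positive) so scores are reproducible across platforms. Each
outline becomes a point in the leading 3 components; a trial is a
trajectory. `stage_distances()` measures, per trial, the Euclidean
distance (in the retained 3 components, matching the 3D shape-space
analysis; full-space distances are available by raising `k`) from the
mean score of the trial's group at that stage — the pooled potter set
or a single community, whose means differ.

## Inference

`permanova()` partitions total squared pairwise Euclidean distance into
among- and within-group parts; the pseudo-F compares them on (a-1,
N-a) df, R² is the among fraction, and significance comes from
permuting group labels: 9,999 random permutations by default with an
explicit seed, or exhaustive enumeration of all distinct relabelings
whenever these number at most 100,000 (the observed labeling counts
itself, so exact p >= 1/total). In the univariate Euclidean case the
pseudo-F is algebraically the classical one-way ANOVA F, which the
tests exploit as an oracle; `vegan::adonis2` serves as an independent
cross-check.

`stage_lmm()` is the convergence test: distance ~ Stage (pre-formed vs
final) with a per-potter random intercept and, by default, a separate
residual SD per potter (`nlme::varIdent`), fitted by ML. The reported
denominator df follows nlme's within-group convention, N - potters - 1.
The residual strata could also plausibly be stages or potter-by-stage
cells; both are available through `stratum`, with the per-potter
stratification as the default.

`community_anova()` implements the Community x Trial repeated-measures
design (subjects are potters); the between-subject Community F uses the
potters-within-community mean square and, with balanced trials, equals
the one-way F on potter means — which is how it can be applied to a
published table of per-potter means. Effect size is generalized
eta-squared (effect SS over effect SS plus all error SS).
`oneway_anova_from_summary()` reconstructs the among-potter one-way F
from per-potter means and CVs (SD = CV x mean / 100), enabling
verification against published summary tables: the packaged money-bank
ESA table gives F(6,28) = 64.28 from rounded inputs. No multiple-testing
correction is applied anywhere; alpha is 0.05 two-sided throughout.

## The synthetic-data generator

`simulate_study()` emulates the study design the analysis assumes:
seven expert potters in two workshop communities (four and three), five
trials per vessel type, and a shared money-bank-like final form (16 cm
high, 14 cm maximal diameter, nearly closed aperture). Each potter
archetype has

* an idiosyncratic **pre-formed shape** (cylindrical, barrel-like,
  squat open, sphere-like with a wide rimmed aperture, ...) — these
  differences are the among-potter signal at stage 0;
* an optional sequence of **waypoints**: the potter's route through
  parameter space;
* a **gesture count range** (5-6 for the fastest worker up to 8-12 and
  10-11 for the slowest, spanning the 5-12 range overall) and
  gamma-distributed inter-gesture intervals calibrated so typical trial
  durations fall around 60-160 s (the fastest potters near 60 s, the
  slowest near 160 s); timing distributions are plausible stand-ins,
  as no distributional description of gesture timing exists to
  calibrate against;
* a persistent **final signature** (`final_offset_scale = 0.02`,
  multiplicative per parameter, derived deterministically from the
  potter id) on the shared final form, small against the pre-form
  spread — this is what makes final shapes much less variable than
  pre-forms while retaining subtle individuality;
* trial-to-trial **noise** (`trial_noise_scale = 0.03`, multiplicative
  Gaussian on parameters, clamped to the valid domain so profiles stay
  geometrically valid).

Profiles come from a superelliptic radius family r(y) anchored at base
radius, maximal radius (at a parametrized relative height) and aperture
radius, with a bulge exponent controlling wall curvature (exponent 2
reproduces circular arcs exactly, so sphere-like bodies are exact) and
an optional rim bulge. Stage parameters interpolate pre-form ->
waypoints -> final + signature linearly, with per-stage noise. Per-trial
seeds are hashed from (study seed, potter, type, trial index), so any
subset is reproducible in isolation.

What the generator does *not* emulate: digitization error and tablet
tracing artefacts, re-entrant profiles (overhanging walls), wheel
kinematics, or any correlation between gesture timing and shape change.
Passing tests on synthetic data therefore validate the statistical
machinery and the direction of the convergence phenomenon, not the
specific effect sizes of any real assemblage.

With these defaults the among-potter R² is near 1 at the pre-formed
stage and drops sharply at the final stage. One deliberate consequence
of keeping the final signature at 0.02 against trial noise 0.03: with
five trials per potter the final-stage permutation test is not
reliably significant, unlike in real assemblages where potter
signatures on final shapes are detectable. The signature-to-noise ratio
of real potters is not recoverable from published summaries, and the
package's validation targets are the direction checks, so the default
was left at the convergence-property bound rather than tuned.

## Problem sizes and determinism

The shipped tests run the full pipeline at reduced sizes chosen for
tight feedback loops (profiles of 48-128 points, 8-15 harmonics,
199-999 permutations, 100-replicate recovery studies, a 1000-dataset
null calibration of the permutation test at 999 permutations each); the
defaults (256 points, 20 harmonics, 9,999 permutations) are what an
analysis of real data would use, and the full default pipeline on a
7 x 5 study completes in seconds. All stochastic steps take explicit
seeds; `run_pipeline()` re-run with the same config writes a
byte-identical JSON report.

## Known limitations

* Re-entrant (overhanging) profiles are rejected rather than modelled;
  the height-parametrized representation cannot express them.
* The exact smoothing filter and harmonic count of any particular real
  study are unknowable from published summaries; both are configurable
  and defaults are documented above.
* ESA excludes the base disc; absolute ESA values are comparable within
  a convention, not across conventions.
* The chi-square reference for boundary variance components is
  conservative; interpret marginal intercept LRTs accordingly.
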