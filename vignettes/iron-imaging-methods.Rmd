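---
title: "Quantifying tumor macrophage iron deposits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor macrophage iron deposits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(femri)
```

## Scientific background

Tumor-associated macrophages (TAMs) accumulate hemosiderin, an aggregated
intracellular iron store with strong magnetic susceptibility. Colonies of
these hemosiderin-laden macrophages form microscopic iron deposits that are
visible both to Prussian-blue histochemistry (ferric iron stains blue) and
to iron-sensitive MRI without any contrast agent: local iron shortens the
effective transverse relaxation time T2\*, so a multi-gradient-echo (MGE)
acquisition converted to a rate map R2\* = 1/T2\* lights up deposits as
high-iron pixel clusters. Because TAM density is highest at the stromal
margin of a tumor and decays toward the core, the *spatial profile* of
deposits along a normalized margin-to-core coordinate is an imaging
biomarker of macrophage infiltration, and its change under CSF1R-inhibitor
immunotherapy (which blocks macrophage accumulation) is a spatially
resolved readout of treatment response.

This package implements that entire analysis chain, plus a seeded
synthetic-phantom generator with known ground truth against which every
stage is validated.

## Signal model and relaxometry fitting

Each pixel of an MGE stack is modeled as a monoexponential decay over the
echo train,

$$ S(TE) = S_0 \, e^{-TE/T_2^*}, \qquad R_2^* = 1000 / T_2^*, $$

with TE and T2\* in ms and R2\* in s^-1. Repetition time and flip angle
(TR 1.2 s, 60 degrees by default) act only on the steady-state amplitude
and are absorbed into S0; the fit uses amplitude decay alone. The default
echo train is 16 echoes at 3 ms spacing (3, 6, ..., 48 ms); only the first
echo time and the echo count of the original acquisition are standard, so
uniform spacing is a configurable default.

`fit_t2star_pixel()` / `fit_t2star_map()` estimate (S0, T2\*) by
log-linear least squares. Two numerical rules matter:

* **Noise-floor truncation.** The echo train is cut at the *first* sample
  at or below `noise_floor` and at least three echoes must remain;
  magnitude samples near the noise floor carry no usable decay
  information and, once log-transformed, would otherwise dominate the
  fit. A practical floor is about three times the noise standard
  deviation.
* **Signal-weighted regression (default).** Log-transforming Gaussian
  noise makes the log-domain variance approximately sigma^2 / S^2, so the
  default fit weights each echo by S^2 -- the standard first-order
  variance correction for log-linear exponential fitting. Unweighted
  ordinary least squares is available via `weighting = "none"`. Both
  variants invert noiseless data exactly; at 2% Gaussian noise on a
  T2\* = 12 ms train the weighted estimator roughly halves the median
  T2\* error (the test suite verifies the sub-5% median-error bound the
  package targets). A nonlinear refinement was considered and rejected:
  the log-linear solution is deterministic, has no starting-value or
  convergence failure modes, and its accuracy is already
  noise-limited at the package's operating conditions.

Pixels that cannot be fitted (fewer than three usable echoes, or a
non-decaying train) carry a sentinel -- `fit_ok = FALSE`, `t2star = Inf`,
`r2star = 0` -- rather than raising an error, because in any real slice
most background pixels are air.

## Iron calibration and parametric maps

Aqueous iron standards follow a linear relation
`r2star = slope * concentration + intercept`; `fit_iron_calibration()`
estimates it by ordinary least squares (delegated to `stats::lm`) and
`apply_calibration()` inverts it per pixel. The intercept is the baseline
relaxation rate of iron-free tissue or solvent, so pixels relaxing more
slowly than baseline map to *negative* concentrations; these are clamped
to zero while keeping their validity flag. Concentration units are mM
throughout (the standards' original units are not public; any linear unit
rescales the calibration slope without affecting downstream counts). The
synthetic default calibration -- slope 30 s^-1/mM, intercept 20 s^-1 -- is
obtained by fitting noiseless synthetic standards, giving background
tissue (T2\* = 50 ms) exactly zero iron.

## High-iron stratification and cluster counting

`high_iron_mask()` stratifies the iron map inside a region of interest.
The phrase "median of the concentration range" admits two readings; both
are implemented:

* `"range-midpoint"` (default): threshold at (min + max) / 2 of the valid
  concentrations in the ROI -- the literal midpoint of the *range*;
* `"value-median"`: the pixel-value median.

Comparison is strictly greater-than, which makes the degenerate
constant-map case unambiguously empty. `label_clusters()` then labels
connected components, 8-connectivity by default (a diagonal neighbour at
0.05-0.1 mm pixels is still within one deposit diameter), with
deterministic raster-scan labeling and an optional minimum size; the
default minimum is a single pixel because one MRI pixel already spans a
multi-cell deposit. The labeling routine is authored in the package
(two-pass union-find) because the installed image stack only provides
4-connectivity labeling; the test suite checks it pixel-for-pixel against
an independent flood-fill oracle under both connectivities.

## Radial infiltration geometry

`tumor_roi()` wraps a tumor cross-section mask with its centroid and
polar-ordered boundary. The infiltration fraction of a point is computed
by centroid-ray normalization: cast the ray from the centroid through the
point to the boundary at distance D and report `f = 1 - d/D`, so f = 0 on
the stromal margin and f = 1 at the centroid. This reproduces the
concentric scaled-contour "rake" geometry of ring-ROI counting tools and
is exact for star-shaped regions; for strongly non-convex outlines a
distance-transform normalization (`normalization = "edt"`) is available.
`make_radial_grid()` partitions the ROI into n equal-width infiltration
bins (deciles by default; bin k covers [(k-1)/n, k/n), last bin closed),
and `infiltration_profile()` assigns each cluster to a bin *by its
centroid* -- deposits are counted, not pixels, so area weighting would
change the meaning of the profile. Counts are reported raw per bin;
per-area normalization is available but off by default.

`compare_profiles()` applies the two-sample Kolmogorov-Smirnov test to the
raw per-deposit infiltration fractions (not the binned counts), which uses
all positional information and is what the package's cross-modality
equivalence checks rely on. R's exact small-sample p-value is used where
available; the tests verify it against exhaustive enumeration.

## Histology and immunofluorescence quantification

Prussian-blue positivity uses a blue-dominance rule: a pixel is positive
when blue exceeds *both* red and green by `delta` (default 30 on the 0-255
scale). This cleanly separates blue deposits from the pink nuclear-fast-red
counter-stain and the white slide background without full stain-vector
deconvolution, which would add an estimation step with no benefit at
typical PB/NFR contrast. Deposits are counted with a physical floor of
20 um^2 (below a single macrophage cross-section); IF cells with a floor
of 25 um^2 and a per-channel intensity threshold.

Co-positivity of iron deposits with AIF1 (M1-like), CD206 (M2-like) and
CSF1R is established by greedy one-to-one nearest-centroid matching within
10 um (about one cell diameter), because re-stained and re-registered
sections retain small residual offsets that defeat strict pixel overlap.
The exhaustive combination counts are *exclusive* categories --
iron+AIF1+ means AIF1-positive and CD206-negative, and so on -- because
the fractional-population denominators (the sum of iron+AIF1+, iron+CD206+
and iron+AIF1+CD206+) only partition the marker-bearing iron+ population
under that reading. A zero denominator leaves fractions undefined (`NA`),
never zero.

## The synthetic ground-truth generator

`sample_deposits()` plants deposits as an inhomogeneous Poisson process
with intensity

$$ \lambda(f) = \lambda_0 \, e^{-f/\tau}, $$

implemented by thinning a homogeneous field, so margin bias is controlled
by a single decay scale tau (default 0.25: density falls ~55-fold from
margin to core, matching the strongly margin-weighted profiles the method
is designed to detect). Deposit radii are gamma distributed (mean 50 um, a
small macrophage colony), concentrations lognormal (median 2 mM, sdlog
0.15, well above tissue background), and marker states independent
Bernoulli draws. These distributional defaults are documented placeholders
-- no quantitative deposit-size or concentration distributions are
published -- chosen so that deposit R2\* (about 80 s^-1) clearly exceeds
background (20 s^-1).

`render_mge()` and `render_pb_histology()` render the *same* truth, so the
modality pair is registered by construction; `render_if_field()` renders
200 um fields with configurable marker probabilities; `simulate_cohort()`
builds two-arm trials in which treatment scales only the accumulation
intensity lambda0 (the drug's primary effect is fewer deposits, not less
iron per deposit). Tumor radii are lognormal and *shared between arms*, so
the planted treatment factor equals the expected end-to-end count ratio;
the separate tumor-growth effect of therapy is deliberately not folded
into the count endpoints. Default MGE noise is Gaussian on magnitude
(sigma 2% of S0); a Rician option exists to stress the fitter, and no
Rician bias correction is applied (a documented non-goal).

What the phantoms deliberately do **not** emulate: susceptibility blooming
and dipole fields around deposits, partial-volume decay-curve mixing,
B0 inhomogeneity, vascular/hemorrhage iron, staining variability and
section-registration error of real re-stained slides. Passing tests
therefore demonstrate the correctness of the *measurement chain* under the
stated forward model, not scanner-level realism.

## Cohort statistics

`treatment_ratio()` reports mean(treated)/mean(control) with a seeded
percentile bootstrap (1000 resamples, animals resampled within arm).
`correlate_counts_volume()` pools both arms into one Pearson regression
(configurable by subsetting), reporting r, r^2 and the two-sided t-test
p-value. `profile_group_comparison()` compares arms per infiltration
decile with Welch t tests and Holm adjustment -- a deliberate, documented
divergence from the original two-way ANOVA with Sidak correction: the
per-decile Welch+Holm table is simpler, assumes no shared variance across
deciles, and standard ANOVA machinery remains available in base R for
users who want the omnibus test.

## Problem sizes and numerical choices

The validation suite and the acceptance script run on desk-scale phantoms
chosen so the full chain executes in minutes on one core: tumors of
~2-3 mm radius; ex vivo MRI at 0.05 mm pixels (~100x100), in vivo at
0.1 mm (~150x150), 16 echoes; Prussian-blue renderings at 8 um/px
(histology-scale 1 um/px rendering is supported but unnecessary for
50 um deposits); IF fields of 200 um at 2 um/px. Cross-modality
equivalence uses 50 seeded replicates; trial re-enactments pool 8-10
seeded replicate cohorts of the original arm sizes (8/group for the MRI
endpoint, 4/group for histology) to stabilize the stochastic effect
estimates.

Ties and edge cases: thresholds use strict inequality; bins are
lower-inclusive with the last bin closed; cluster labels are assigned in
raster order of each component's first pixel, making label images
reproducible bit-for-bit; all generators are pure functions of
(configuration, seed).

## Known limitations

* **Cluster merging.** Two deposits closer than one pixel (MRI) or than
  the sum of their radii (histology) are counted once. At the default
  densities this loses a few percent of deposits and, because the control
  arm is denser, biases the measured treated:control ratio slightly
  upward (1-2 percentage points at the default in vivo resolution). This
  is a property of cluster counting itself, shared with the original
  image-analysis tools, not of the synthetic design.
* **Ray normalization** assumes a star-shaped ROI; for strongly
  non-convex tumors use `normalization = "edt"`.
* **Magnitude-noise bias.** Gaussian fitting of Rician magnitudes is
  biased at low SNR; the noise-floor truncation mitigates but does not
  remove this, and no Rician correction is applied.
* The synthetic effect-size re-enactments recover *planted* effects; they
  validate the pipeline's ability to measure a known truth, not the
  biology of any particular trial.
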