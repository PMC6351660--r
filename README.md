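# femri — quantitative iron imaging of tumor macrophage infiltration

Tumor-associated macrophages (TAMs) store iron as hemosiderin, and
colonies of these iron-laden cells form microscopic deposits that can be
imaged twice over: by Prussian-blue histochemistry (ferric iron stains
blue) and — without any contrast agent — by iron-sensitive MRI, where
local iron shortens T2\* and high-iron pixel clusters appear on
R2\* = 1/T2\* maps. Because TAMs concentrate at the stromal margin of a
tumor, the radial profile of deposit counts from margin to core is a
spatial biomarker of macrophage infiltration and of response to
macrophage-targeted (CSF1R-inhibitor) immunotherapy.

`femri` implements the full analysis chain for both modalities, for
scientists doing preclinical imaging of TAM biology:

* **Relaxometry** — pixel-wise monoexponential fitting of multi-gradient-
  echo (MGE) stacks, `S(TE) = S0·exp(−TE/T2*)`, with noise-floor
  truncation of the echo train and signal-weighted log-linear least
  squares; linear iron calibration `R2* = a·[Fe] + b` from standards;
  parametric iron-concentration maps (mM).
* **Segmentation** — binary stratification of iron maps at the midpoint of
  the concentration range (or the value median) and deterministic
  connected-component cluster counting (4/8-connectivity, minimum size).
* **Spatial profiling** — tumor ROI geometry, the normalized infiltration
  fraction (0 = stromal margin, 1 = centroid) by centroid-ray casting,
  concentric "rake" decile grids, per-deposit profiles, and two-sample
  Kolmogorov–Smirnov profile comparison.
* **Histology / IF quantification** — Prussian-blue positivity by
  blue-dominance, deposit counting with physical size floors, per-channel
  cell detection, iron⁺/AIF1/CD206/CSF1R co-positivity by centroid
  matching, and fractional macrophage populations.
* **Synthetic phantoms** — seeded ground-truth tumors with margin-decaying
  deposit density `λ(f) = λ0·exp(−f/τ)`, paired MGE / Prussian-blue /
  immunofluorescence renderings of the *same* truth, and two-arm
  control-vs-treated cohort simulation.
* **Cohort statistics** — treated:control ratios with bootstrap CIs,
  Pearson correlation of cluster burden with tumor volume, per-decile
  Welch + Holm group comparisons.

## Worked example

Plant a synthetic tumor, image it with both modalities, and test whether
the two infiltration profiles agree:

```r
library(femri)
set.seed(42)

truth <- sample_deposits(random_blob_geometry(2, seed = NULL),
                         lambda0 = 8, tau = 0.25, seed = NULL)
truth
#> Synthetic truth: 37 deposits over 12.6 mm^2 (lambda0 8 /mm^2, tau 0.25)

cal <- default_iron_calibration()
cal
#> Iron calibration: R2* = 30 * [Fe] + 20  (R^2 = 1.0000, n = 6)

mr  <- render_mge(truth, cal = cal,
                  acq = acquisition_params(pixel_size = c(0.05, 0.05)),
                  seed = NULL)                    # 2% Gaussian noise
res <- analyze_femri(mr)    # fit T2* -> iron map -> threshold -> clusters
res$iron
#> Iron map: 107 x 107 pixels, 5046 valid
#>   concentration range 0..2.72 mM (valid pixels)
res$clusters
#> Cluster set: 33 clusters (connectivity 8, min size 1 px)

prof_mr <- profile_analysis(res, modality = "FeMRI")
prof_mr
#> Radial profile [FeMRI]: 33 deposits over 10 bins
#>   counts (margin -> core): 14 3 11 2 1 1 0 0 1 0

pb      <- render_pb_histology(truth, seed = NULL)
prof_pb <- profile_analysis(analyze_pb(pb), modality = "PB")
prof_pb
#> Radial profile [PB]: 33 deposits over 10 bins
#>   counts (margin -> core): 13 4 9 4 1 1 0 0 1 0

ks <- compare_profiles(prof_mr, prof_pb)
sprintf("KS D = %.3f, p = %.3f", ks$statistic, ks$p_value)
#> "KS D = 0.152, p = 0.851"
```

Of 37 planted deposits, 33 survive the strict high-iron threshold and
cluster merging in *both* modalities; the margin-heavy decile profiles
from MRI and histology are statistically indistinguishable (KS p = 0.85),
which is the cross-modality equivalence the method rests on. Cohort-level
analyses follow the same pattern via `simulate_cohort()` and
`summarize_cohort()`; a thin command-line front end lives at
`inst/cli/femri.R` (`simulate`, `calibrate`, `ironmap`, `clusters`,
`profile`).

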