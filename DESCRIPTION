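Package: femri
Title: Quantitative Iron MRI and Histology Profiling of Tumor Macrophage
    Infiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contrast-agent-free iron imaging analysis for tumor-associated
    macrophage (TAM) studies. Fits pixel-wise monoexponential T2*/R2* decay
    to multi-gradient-echo (MGE) image stacks, converts R2* maps to
    parametric iron-concentration maps through a linear calibration against
    iron standards, stratifies the maps into high-iron binary masks,
    counts connected high-iron pixel clusters, and profiles cluster or
    histological deposit counts along a concentric "rake" grid of radial
    infiltration deciles from the stromal margin to the tumor core.
    Companion routines quantify Prussian-blue stained histology and
    multiplexed immunofluorescence fields (marker co-positivity and
    fractional macrophage populations), generate fully seeded synthetic
    phantoms with known ground truth (paired MGE / histology renderings and
    control vs. treated cohorts), and compute cohort-level statistics
    (treatment-effect ratios with bootstrap confidence intervals, Pearson
    correlation of cluster burden with tumor volume, per-decile group
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
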