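Package: iltwss
Title: Wall Shear Stress Indices and Intraluminal Thrombus Co-Localization for Aortic Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing toolkit for computational hemodynamics of abdominal
    aortic aneurysms. Computes per-vertex wall-shear-stress derived indices
    (TAWSS, OSI, TransWSS, RRT, ECAP) from pulsatile WSS vector time series on
    triangulated luminal surfaces, estimates intraluminal thrombus thickness
    from paired lumen and outer-thrombus surfaces by minimum Euclidean distance
    with a wall-thickness mask, regionalizes the thrombus by thickness, and
    quantifies co-localization of hemodynamic indices with thrombus via
    literature thresholds and Spearman rank correlation. Includes a
    Carreau-Yasuda shear-thinning blood viscosity model, Fourier-series
    inflow-waveform fitting, grid-convergence-index verification utilities, and
    a synthetic-data generator with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
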