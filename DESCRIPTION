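Package: lgkinetics
Title: Quantitative Analysis of Blood Progenitor Kinetics in the Drosophila Lymph Gland
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term live imaging of the Drosophila
    larval lymph gland. Normalizes dual-reporter (dome-MESO-GFP / eater-dsRed)
    single-cell intensity tracks, classifies differentiation trajectories as
    sigmoid or linear and estimates differentiation rates; quantifies mitosis
    kinetics and orientation in a cylindrical organ frame (rho- vs z-mitosis,
    angle to the heart tube, Q-Q normality of orientations); builds aligned
    5x5 spatial event heat maps and compares them by correlation category;
    performs histo-cytometry (LoG nucleus detection, seeded subsampling,
    quadrant gating) on two-channel images; and calls FUCCI cell-cycle phases
    from two-channel traces. A synthetic-data generator with ground-truth
    labels emulates the statistical structure of the recordings so every
    stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
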