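Package: centriodyn
Title: Centriole Ring Geometry, Recruitment Dynamics and Peak Counting
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of centriole distal-end protein dynamics
    from live-imaging experiments in syncytial fly embryos. Fits elliptical
    annular Gaussian profiles to super-resolution images of end-on centriolar
    rings and filters poorly oriented centrioles by ring eccentricity; turns
    per-centriole fluorescence-intensity tracks into per-embryo recruitment
    profiles and fits four candidate temporal models (Lorentzian, Gaussian,
    increase-constant-decrease, increase-decrease) selected by the Bayesian
    Information Criterion; extracts peak intensity, absolute and S-phase
    normalized peak centres, cartwheel-growth parameters (rate, period, size)
    and oscillation amplitude/centre; correlates peak timing with S-phase
    length; and implements peak counting spectroscopy (threshold calibration,
    supra-threshold peak counting, ROUT robust outlier screening). A synthetic
    data generator with stored ground truth drives validation of every
    estimator, and a seeded pipeline orchestrates simulate-fit-report runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
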