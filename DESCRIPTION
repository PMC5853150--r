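Package: amclear
Title: Clearance Kinetics of Black Carbon in Airway Macrophages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the clearance kinetics of black carbon (BC)
    in airway macrophages (AM) sampled by induced sputum. Provides image-based
    quantification of carbon area per cell with pixel-to-micron calibration,
    a Bayesian hierarchical single-exponential decay model of AM BC over time
    fitted by MCMC, DIC model comparison, posterior predictive checks with
    loess-smoothed group profiles, clearance half-life derivation, and
    method-agreement statistics (Bland-Altman, Spearman, ICC). A synthetic
    cohort and synthetic micrograph generator emulates the longitudinal panel
    design so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    yaml,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
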