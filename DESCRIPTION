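Package: cacycle
Title: Calcium-Cycling Modelling and Quantification for PKP2-Deficient
    Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voltage-clamped compartmental model of calcium cycling in the
    mouse ventricular myocyte with a control parameter set and a variant
    emulating cardiomyocyte-specific plakophilin-2 (PKP2) deficiency
    (reduced calsequestrin, slowed L-type channel inactivation, reduced
    L-type current density and ryanodine-receptor flux).  Includes the
    voltage-clamp protocols used to characterise the variant
    (current-voltage relation, excitation-contraction coupling gain,
    caffeine-evoked sarcoplasmic-reticulum load, pacing), feature
    extraction for calcium transients, line-scan spark detection,
    ratiometric calcium calibration, Hill fits of ryanodine-binding
    curves, ECG interval correction, dyad ultrastructure quantification
    (nearest-boundary distances, T-tubule skeleton orientation, cluster
    overlap) and the group-comparison statistics used throughout, all
    exercisable on seeded synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
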