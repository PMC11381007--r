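Package: fibrocast
Title: Micro-CT Lung Densitometry and Histomorphometry for Murine
    Pulmonary Fibrosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification pipeline for bleomycin-induced
    pulmonary and cutaneous fibrosis studies in the mouse. Converts
    respiratory-gated micro-CT volumes from grey levels to Hounsfield
    units with a two-anchor linear calibration, segments the total lung,
    computes per-phase densitometric readouts (lung volume, mean lung
    attenuation, gas content) and aeration-compartment fractions
    (normo-, hypo- and non-aerated), and derives cross-phase structural
    biomarkers such as the tissue volume. Companion histomorphometry
    tools aggregate Ashcroft fibrosis scores into severity frequency
    distributions, quantify stain-positive area fractions and skin layer
    thicknesses, and normalise immunofluorescence readouts as fold
    increases over control. A synthetic paired-phase lung phantom
    generator with exact ground truth supports validation of every stage,
    and a reporting layer provides group summaries, ANOVA with the usual
    post hoc procedures, and osmotic mini-pump dose arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    tiff,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
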