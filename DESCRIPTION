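Package: dynpet
Title: Dynamic PET Quantification and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of dynamic positron emission tomography (PET)
    brain studies with metabolite-corrected arterial parent-plasma input
    functions, and the statistics needed to characterise test-retest
    reliability of the resulting binding measures. Implements six
    quantification families (reversible one- and two-tissue compartment
    models with fitted blood volume, Logan graphical analysis, non-negative
    least squares spectral analysis, standardised uptake values, and the
    simplified reference tissue models SRTM/SRTM2), each regionally and/or
    voxelwise, together with test-retest difference, between-subject
    coefficient of variation and one-way single-measures intraclass
    correlation summaries. A deterministic dynamic-phantom generator with
    known ground truth supports end-to-end validation without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
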