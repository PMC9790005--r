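Package: drmage
Title: Diagonal Reference Models for DNA Methylation Age Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying lifecourse socio-economic position and social
    mobility in relation to epigenetic aging. Evaluates linear DNA-methylation
    age predictors (epigenetic clocks) on beta-value matrices, estimates white
    blood cell composition by reference-based constrained projection, derives
    age-acceleration residuals adjusted for chronological age, plate batch and
    cell composition, encodes origin/destination social class and mobility
    contrasts, and fits diagonal reference models with a profile-likelihood
    estimator of the origin/destination mixing weight. Includes descriptive
    cross-tabulations, restricted mobile-versus-immobile comparisons, and a
    synthetic cohort generator mirroring the origin-by-destination class
    structure of the UK Household Longitudinal Study epigenetics subsample.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
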