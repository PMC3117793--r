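Package: pinnasonar
Title: Information Transfer of Moving-Pinna Sonar Localization in CF Bats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian template-matching model of sound localization by
    constant-frequency echolocating bats that scan returning echoes with
    moving pinnae. Discretizes the frontal hemisphere into equal-area
    directional cells, synthesizes frequency-dependent emission and hearing
    directivity fields (including a two-isotropic-source control emitter),
    builds binaural amplitude-modulation templates from an anti-phase ear
    sweep, and quantifies localization performance in bits of Shannon
    entropy of the marginalized posterior over echo directions under
    structured flutter noise. Includes estimation of the flutter-noise
    covariance from simulated echo ensembles (Goertzel single-bin spectral
    power) and a Monte Carlo simulation of perch hunting that folds in
    spherical spreading and ISO 9613-1 atmospheric attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
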