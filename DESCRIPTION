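Package: thnflow
Title: Fractional Couple-Stress Casson Tri-Hybrid Nanofluid Channel Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form Atangana-Baleanu time-fractional solutions for the
    unsteady generalized Couette flow of a couple-stress Casson nanofluid
    carrying three differently shaped nanoparticle species (a tri-hybrid
    suspension) in a blood base fluid. Provides shape-dependent mixture
    correlations for the suspension's thermophysical properties, numerically
    robust evaluation of the Mittag-Leffler and Robotnov-Hartley functions,
    finite sine-Fourier series temperature and velocity fields, an
    independent Laplace-domain numerical-inversion oracle for
    cross-validation, and wall heat-transfer post-processing (Nusselt
    number, heat-transfer enhancement tables, skin friction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
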