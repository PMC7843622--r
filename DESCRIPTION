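Package: posidose
Title: Dosimetry, Clonogenic Survival and Nanodosimetric Track Simulation
    for Positron-Emitting Radionuclides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the therapeutic potential of positron
    (beta-plus) emitting radionuclides in vitro. Implements decaying-source
    absorbed-dose calculations for uniformly mixed radionuclide solutions
    (cumulated activity, dose, dose-rate profiles and inverse activity
    planning), clonogenic-assay reduction with linear-quadratic survival
    fitting and relative biological effectiveness (RBE) at a stated survival
    level, and a parameterized event-by-event track-structure Monte Carlo for
    sub-keV electrons and positrons in water, with DNA single- and
    double-strand-break scoring on a linear 100-base-pair DNA model. A
    synthetic-data module generates colony-count tables and deposition-event
    streams with known ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
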