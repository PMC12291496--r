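Package: teinvade
Title: Transposable-Element Invasion Dynamics and Gaussian-Process Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Individual-based forward simulation of a P-element invasion in an
    obligately outcrossing diploid population under the piRNA-cluster trap
    model, with a beta-distributed distribution of fitness effects (DFE) for
    new insertions. Includes closed-form and numerical DFE summaries with a
    drift-based selection-efficacy classification, a multi-task Gaussian
    process surrogate that emulates the simulator across its parameter space,
    Latin hypercube designs, and an NRMSE-based calibration procedure that
    ranks parameter combinations against replicated copy-number time series.
    Pseudo-empirical data generators make the full inference chain testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    jsonlite,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
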