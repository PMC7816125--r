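Package: imeswitch
Title: Hybrid Dynamical Model of the Yeast IME1 Promoter lncRNA Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the regulatory circuit controlling meiotic entry in
    budding yeast, in which the long noncoding RNA IRT2 both activates (via a
    hysteretic threshold latch) and dose-dependently represses the repressor
    lncRNA IRT1, which in turn represses the master regulator IME1. Provides
    an event-aware hybrid ODE integrator with a closed-form oracle for the
    unrepressed cascade, analytic and numerical steady-state solvers with
    Rme1 dose-response sweeps and switch-shape metrics, generators for
    synthetic noisy time courses and single-cell mRNA copy-number
    populations, and least-squares parameter recovery on synthetic data.
    All results are tibbles with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
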