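Package: snitr
Title: Rumor Propagation Dynamics with the SNITR Compartmental Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of online-rumor spread with the
    SNITR (Susceptible-Neglected-Infected-Transmitter-Recovered)
    compartmental model. Provides the mean-field ODE system and
    deterministic trajectory integration, closed-form and numeric
    equilibria with consistency diagnostics, next-generation-matrix
    reproduction numbers, Jacobian/Routh-Hurwitz local stability
    analysis and empirical global-convergence checks, parameter sweeps
    and reproduction-number sensitivity grids, delayed counter-rumor
    (transmitter) intervention experiments, synthetic binned repost
    time-series generation, and bounded multi-start least-squares
    parameter estimation from observed infected-plus-transmitter
    series. All results are returned as tibbles with broom-style
    tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
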