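Package: slsfit
Title: Finite-Loading-Rate Standard Linear Solid Analysis of Stress
    Relaxation and Creep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing viscoelastic materials (hydrogels,
    soft tissues, polymers) from ramp-hold stress-relaxation and creep
    tests using the standard linear solid (Zener) model. Provides
    closed-form solutions of the loading ramp and hold phases that
    account for the finite loading rate of real testing machines,
    alongside the traditional step-loading (infinite-rate) solutions;
    nonlinear least-squares estimators that recover the moduli E1 and E2
    and the viscosity eta from measured hold curves, optionally with a
    stretched-exponential (Kohlrausch) decay; a material-point simulator
    with an independent ODE oracle for generating benchmark curves; and
    a batch pipeline that maps estimation error against loading rate to
    locate the rate threshold above which each equation form is
    accurate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
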