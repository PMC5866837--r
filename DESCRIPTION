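Package: pbkrd
Title: Physiologically Based Kinetic Modelling-Based Reverse Dosimetry for
    Estrogenic Chemicals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A minimal physiologically based kinetic (PBK) model of a
    chemical in the rat, parameterized entirely from in vitro and in silico
    inputs, used to translate in vitro estrogenicity concentration-response
    curves into predicted in vivo dose-response curves. Covers
    substrate-depletion intrinsic clearance estimation from liver S9
    incubations, fraction-unbound determination from rapid equilibrium
    dialysis, tissue:blood partition coefficient estimation from log Pow,
    Caco-2-based intestinal absorption, reverse dosimetry against the
    predicted blood Cmax, Hill fitting of concentration-response data,
    benchmark-dose (BMD) analysis with an exponential model for continuous
    endpoints, and local sensitivity analysis.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
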