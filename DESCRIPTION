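Package: editscreen
Title: Analysis of Dual-Luciferase RNA Editing Reporter Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for high-throughput small-molecule screens run with a
    dual-luciferase A-to-I RNA editing reporter, in which an editing-dependent
    nanoluciferase (Nluc) channel is normalized to a constitutive firefly
    luciferase (FFL) channel. Provides 384-well plate input/output and
    acoustic-dispense dilution arithmetic, Z'-factor plate quality control,
    per-plate control normalization to percent inhibition, a cytotoxicity
    filter on the FFL channel, hit and activator calling, four-parameter
    logistic dose-response confirmation, quantification of editing from
    Sanger chromatogram peak heights (G/(A+G)), fold-change comparisons for
    perturbation experiments, and a mechanistic simulator of reporter screens
    for validation and power analysis.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
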