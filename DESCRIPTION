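Package: transmix
Title: Transmission Assortativity from Who-Infected-Whom Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates group-level transmission assortativity (the gamma and
    delta coefficients) from transmission-chain line lists, with exact
    Clopper-Pearson confidence intervals propagated from the within-group
    transmission proportion. Includes a discrete-time, group-structured
    branching-process outbreak simulator, a scenario-ensemble sampler
    emulating nosocomial outbreak settings, and an evaluation harness
    measuring estimator bias, interval coverage, sensitivity and specificity
    over analysis windows defined relative to each group's epidemic peak.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
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
RoxygenNote: 7.3.3
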