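Package: protonrv
Title: In-Silico Comparison of Prompt Gamma Imaging and Range Probing for
    Proton Range Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis pipeline for comparing two
    proton-therapy range verification systems: prompt gamma imaging (PGI)
    with a knife-edge-slit camera and range probing (RP) with a multi-layer
    ionization chamber. Builds a synthetic layered head phantom and pencil-
    beam scanning spot plans, applies anatomical-change and setup-error
    deviation scenarios, forward-models both detector signals with seeded
    noise, extracts spot-wise range shifts by least-squares fall-off
    matching, converts geometric shifts to water-equivalent thickness, and
    scores per-scenario accuracy and precision with inverse-variance
    weighted statistics.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
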