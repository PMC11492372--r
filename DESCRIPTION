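Package: poresignal
Title: Empirical Modelling of Ionic Current and EDL Potential Signals in
    Solid-State Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling for resistive-pulse sensing with
    metal-layered solid-state nanopores. Predicts the baseline-state
    electrical-double-layer (EDL) potential and transmembrane ionic current
    from the electrolyte composition (Debye activity coefficients, a
    Knudsen-ratio size-partition coefficient) and the pore geometry; predicts
    the perturbed-state current and EDL-potential signals produced by a
    translocating analyte from its radius and valence charge; estimates
    in-pore mobility and diffusivity from translocation times; and inverts
    measured signal pairs by grid search to recover analyte radius and charge.
    Includes a synthetic event-table and current-trace generator with
    FDHM-based event extraction for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
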