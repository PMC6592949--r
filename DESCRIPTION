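Package: breathephys
Title: Breathing-Cycle and Hippocampal Electrophysiology Analysis for Mouse Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-body plethysmography and in vitro
    electrophysiology recordings from mouse disease models. Converts raw
    plethysmography traces into inter-breathing-cycle-interval (ICI)
    distributions via double-threshold trinarization, smoothing and
    cycle-onset detection; discriminates animal groups with Cliff's Delta
    effect-size distances, cosine-distance hierarchical clustering and exact
    binomial significance. Detects spikes and postsynaptic currents by
    noise-scaled thresholding, quantifies drug effects, population bursts,
    charge densities, excitation/inhibition balance and paired-trace
    synchrony, estimates the GABA-A driving force from single-channel
    current-voltage data, and summarises mGluR-dependent long-term depression
    from fEPSP slopes. Includes seeded synthetic-data generators that emulate
    every signal class with known ground truth.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
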