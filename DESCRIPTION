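Package: vicarious
Title: Analysis Pipeline for Emotional-Contagion Experiments in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis chain of dyadic emotional-contagion
    experiments: preprocessing of 20 Hz pupillometry and locomotion traces
    (blink-artifact removal, Savitzky-Golay smoothing, trial epoching,
    baseline normalization, zero-condition subtraction), psychometric
    sigmoid fitting with threshold extraction and assumption-driven group
    comparisons, brain-wide c-Fos density activation screens and
    interregional co-activation statistics, observer-demonstrator dyad
    coupling tested against a shuffled-pairing (derangement) surrogate
    null, and hub/authority analysis of weighted directed anatomical
    connectomes with Leiden partitioning and a node-resampling bootstrap.
    Includes seed-controlled synthetic-data generators that emulate the
    experimental design (stimulus ladders, sigmoid intensity-response,
    blink artifacts, lognormal regional c-Fos densities with planted group
    and dyad effects, modular connectomes) plus Fourier phase scrambling
    and vertical inversion of stimulus frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
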