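Package: hashmix
Title: Demultiplexing Hashtag-Oligonucleotide Data with Negative
    Binomial Regression Mixture Models
Version: 0.1.0
Authors@R: person("Maintainer", "hashmix", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Demultiplexes droplet-based single-cell RNA-seq experiments in
    which samples were tagged with hashtag oligonucleotides (HTOs) before
    pooling. For each HTO a two-component negative binomial regression
    mixture model is fitted by expectation-maximization, using the number of
    detected genes per droplet as an explanatory variable for the HTO
    counts. Droplets are probabilistically classified as single-sample
    droplets, multi-sample multiplets, negatives, or uncertain, with joint
    error probabilities and an overlap-score quality metric per HTO. A
    synthetic-data generator, signal-attenuation and doublet-injection
    benchmark transforms, and the associated precision/sensitivity metrics
    are included, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
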