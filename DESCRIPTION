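Package: placeseq
Title: Place-Cell Ensemble Analysis: Rate Maps, Replay Decoding, Theta
    Sequences and Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis stack for hippocampal place-cell ensembles recorded
    on a square track with flanking rest sessions. Builds adaptive-smoothed
    open-field and direction-split linearized rate maps; classifies brain
    state from LFP spectra and detects sharp-wave ripples and multi-unit
    activity bursts; scores cell-pair reactivation across PRE/RUN/POST;
    decodes candidate replay events with a Bayesian population decoder,
    fits circularly wrapped linear trajectory bands and assesses them
    against cell-identity and rate-map shuffle nulls; quantifies theta
    sequences with a probability-weighted circular-linear correlation and
    single-cell phase precession. A synthetic-session generator with known
    ground truth (place fields, phase precession, theta compression,
    embedded replay) makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
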