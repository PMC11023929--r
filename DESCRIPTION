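Package: dentate
Title: Detection and Analysis of Dentate Spikes and Sharp-Wave Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for hippocampal laminar local field
    potential (LFP) events. Detects dentate spikes (DS) and sharp-wave
    ripples (SPW-R) from multichannel recordings, classifies DS subtypes
    (DS1/DS2) by current source density profiles with PCA and
    density-based clustering, computes peri-event firing-rate statistics
    with shuffle nulls, quantifies brain-wide coupling by discretized
    mutual information with Monte-Carlo significance, decodes position
    from place-cell ensembles by Bayes rule with a Poisson likelihood,
    fits replay-trajectory slopes by circular-linear regression, and
    measures population-vector similarity of event-locked ensembles.
    Includes a synthetic-session generator with full ground truth so
    every stage is verifiable against known event times, tuning curves
    and replay slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
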