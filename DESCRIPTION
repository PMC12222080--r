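Package: tvgc
Title: Time-Varying Granger Causality Networks for Event-Locked EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window pairwise Granger causality analysis of
    event-locked multichannel EEG, from continuous recordings to
    group-level statistics. Provides a synthetic-session generator with
    known directed vector-autoregressive coupling, band-limited
    preprocessing and epoching, AIC-guided autoregressive model-order
    selection, directed connectivity matrices per sliding window,
    weighted directed-graph metrics (node strength, clustering, global
    efficiency, characteristic path length) aggregated into intrinsic
    functional networks, and a three-tier statistical comparison
    (Welch tests, mixed-design ANOVA, node-level follow-ups) with
    Benjamini-Hochberg false discovery rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
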