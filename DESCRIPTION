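Package: crossmapr
Title: Crossover-Point Mapping for Site-Specific Recombination from
    Randomized-Library Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to locate the strand-exchange (crossover) point of a
    site-specific recombination reaction from deep sequencing of a
    randomized-base site library. Each molecule of the library carries a
    single random base at one of P designated positions; after
    intermolecular recombination the randomized positions segregate
    between the two hybrid junction sites of the cointegrate, and the
    boundary at which they split is the crossover point. The package
    provides the library design model and its closed-form base
    distribution, a forward simulator of integrase reactions (second
    strand exchange versus replicative Holliday-junction resolution,
    orientation-dependent outcomes, strand-marker tracing of mismatched
    covalent circles, and sequencing-read generation), an amplicon
    profiling pipeline (read classification, anchor-based window
    extraction, per-position base-frequency profiles), a maximum
    likelihood changepoint estimator of the crossover boundary with
    per-position sequence-stringency tests, and count-based estimators
    for plate assays (recombination frequencies with Wilson intervals,
    adjusted activities, fold changes, restriction-profile summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
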