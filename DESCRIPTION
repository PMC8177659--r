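Package: ibiqc
Title: Quality Control and Resting Heart-Rate Variability for Telemetered
    Inter-Beat Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening inter-beat-interval (IBI) streams recorded
    by externally mounted heart-rate telemetry on free-ranging mammals and
    for estimating resting heart-rate variability from them. Emulates the
    default artefact correction of consumer heart-rate belt software
    (deletion of spurious beats, interpolation of missing beats), detects
    the uncorrectable interpolation artefacts it leaves behind (runs of
    identical IBIs, "flats", and runs of identical non-zero successive
    differences, "stairs"), segments traces into 5-minute windows
    time-matched to Inactive/Active behavioural labels, applies retention
    filters, and computes rMSSD, artefact/flats-stairs classification
    matrices and Bland-Altman agreement between paired IBI streams. A
    synthetic-data module generates seal-like IBI traces with controllable
    rMSSD and realistic corruption (missed beats, spurious beats,
    transmission dropouts), and a Monte-Carlo module quantifies how
    increasing proportions of flats or stairs bias rMSSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
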