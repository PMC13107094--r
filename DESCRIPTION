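Package: imcoh
Title: Intermuscular EMG-EMG Coherence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frequency-domain analysis of paired surface electromyography
    (EMG) recordings: burst onset detection against a pre-stimulus baseline,
    segment screening for sustained activity, zero-padded discrete Fourier
    transform estimation of auto- and cross-spectra, coherence with
    segment-count-based confidence limits, cumulant density, pooling across
    records, a chi-squared extended difference-of-coherence test, Fisher
    transformed frequency-band summaries, and crosstalk diagnostics. A
    synthetic-EMG generator with a configurable common narrowband drive
    provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
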