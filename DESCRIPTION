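Package: asmebci
Title: Auditory Stream-Segregation Multiclass ERP BCI Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing auditory stream-segregation
    multiclass event-related-potential (ERP) brain-computer interface
    experiments. Generates interleaved oddball stimulus sequences
    (ASME-4stream, ASME-2stream, single-stream oddball), simulates
    continuous 64-channel EEG + 2-channel EOG recordings with
    attention-dependent ERP components (N200, P300, N700), ocular
    artifacts and 1/f background noise, removes EOG artifacts by
    PCA + FastICA with correlation-based component zeroing, computes
    signed-r2 discriminability maps and bootstrap estimates of P300
    peak amplitude and onset latency, decodes the attended stimulus
    with shrinkage-LDA (binary AUC under chronological cross-validation
    and a four-class trial-level BCI simulation), and reports
    information transfer rates, binomial significance thresholds and
    NASA-TLX weighted workload scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
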