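Package: envdecode
Title: Backward Decoding of the Speech Envelope from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of the temporal speech envelope from multichannel
    EEG with a lagged ridge-regression backward decoder (temporal response
    function, backward model). Provides band-specific zero-phase FIR
    preprocessing, Hilbert-envelope extraction, five-fold cross-validated
    regularization sweeps, a time-reversed-envelope chance-level model with
    Wilcoxon signed-rank response detection, nonparametric group statistics
    with uncapped Benjamini-Yekutieli adjustment, and a forward-model
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
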