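Package: nirspain
Title: Pain-State Decoding from Functional Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and decodes evoked clinical pain from multi-channel
    functional near-infrared spectroscopy (fNIRS) recordings. Provides a
    40-channel bilateral prefrontal/somatosensory probe model, a synthetic
    cold-stimulation protocol generator with canonical hemodynamic responses
    and physiological noise, a modified Beer-Lambert preprocessing chain
    (optical density, zero-phase band-pass, chromophore inversion, quality
    control), sliding-window feature-cube assembly with causal streaming
    normalization, six small neural-network classifier families trained with
    class-reweighted cross-entropy for pain detection (2-class) and
    left/right pain localization (3-class), a cross-validated evaluation
    suite (sensitivity, specificity, likelihood ratios, Cohen's kappa,
    confusion-matrix reconstruction from summary statistics), and a
    simulated real-time streaming engine emitting newline-delimited JSON
    frames.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
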