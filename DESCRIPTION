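Package: maxsleep
Title: Efficient Max-Pooled Attention Sleep Staging from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end framework for automatic sleep stage classification
    from single-channel EEG. Thirty-second epochs sampled at 100 Hz are scored
    into the five AASM stages (W, N1, N2, N3, REM) by a multi-scale
    convolutional feature extractor, a Transformer sequence encoder whose key
    and value token sequences are shortened by strided max pooling
    ("MaxFormer" attention), and a temporal attention-pooling classifier fused
    across scales. Training follows a two-phase procedure: supervised
    contrastive pre-training of the encoder on augmented multiview batches,
    then fine-tuning of the classifier with the encoder frozen. The package
    also provides an analytic FLOPs model for standard versus max-pooled
    encoder layers, AASM preprocessing (resampling, 0.3-35 Hz band-pass,
    R&K-to-AASM label harmonization, wake trimming), a minimal EDF
    reader/writer, a seeded synthetic polysomnography generator with
    stage-specific spectral signatures, and the usual agreement metrics
    (confusion matrix, per-class F1, macro-F1, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr
Config/testthat/edition: 3
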