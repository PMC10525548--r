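Package: tricap
Title: Three-Slot Caption Generation for Radiology Images with a
    Transformer Encoder-Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for generating structured three-word
    textual descriptions (exam type, body part, identified problem) of
    radiology images. Provides keyword-frequency corpus curation with
    stratified train/validation/test splits, a pluggable convolutional
    feature-extraction backbone with seeded augmentation, a transformer
    encoder-decoder caption model trained by sparse categorical
    cross-entropy under a menu of gradient optimizers, slot-wise
    confusion-matrix evaluation with one-vs-rest per-class metrics,
    unigram-precision BLEU-1 scoring, and a synthetic corpus generator
    whose images deterministically encode their caption triple.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
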