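Package: vaxstance
Title: Monitoring Negative Stance Towards Vaccination in Short Social-Media Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for monitoring stance towards vaccination in
    short social-media messages, with a focus on detecting messages with a
    negative stance. Provides corpus filtering (retweets, URLs, off-topic
    blacklist), inter-annotator agreement analysis (percent agreement,
    Krippendorff's nominal alpha with missing values, per-category mutual
    F-scores), harmonization of doubly-annotated data into strict/lax/one
    reliability tiers at four label granularities, binary word n-gram features
    over a frequency-capped vocabulary, multinomial naive Bayes and linear
    support-vector classifiers with calibrated per-class probabilities, a
    lexicon-based polarity scorer with threshold calibration, precision- and
    recall-oriented ensembles, and a cross-validated evaluation battery with
    random baselines, threshold sweeps and learning curves. A synthetic-corpus
    generator with controlled class distribution, agreement rate and lexical
    signal strength makes every stage testable without access to the original
    annotated tweets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
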