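Package: longicog
Title: Longitudinal Cognitive-Status Prediction with Attention-Based
    Missing-Data Encoders and a Gated LSTM Late-Fusion Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting future cognitive status (cognitively
    normal, amnestic mild cognitive impairment, or Alzheimer's disease
    dementia) from multi-year longitudinal clinic-visit records.  The
    package implements eligibility filtering and reversion exclusion for
    longitudinal cohorts, prefix data augmentation, patient-level k-fold
    splitting, dual "baseline" (z-scored against the cognitively normal
    training population) and "change" (ratio against the first visit)
    feature engineering with explicit missingness masks, two
    missing-data feature encoders (masked scaled-dot-product attention
    and a lighter linear-attention reweighting with a -1 sentinel), a
    gated LSTM late-fusion classifier trained with AdamW, and a
    one-vs-rest evaluation harness with cross-fold t confidence bands.
    A seeded synthetic-cohort simulator emulating the structure of
    longitudinal dementia registries is included so the full pipeline is
    testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
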