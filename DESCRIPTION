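Package: earstage
Title: Scalp-to-Ear EEG Transfer Learning for Automatic Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic sleep staging from single-channel EEG with
    gradient-boosted decision trees, focused on transfer from scalp EEG to
    ear-EEG. Implements preprocessing (resampling, band-pass filtering,
    30-second epoching), a per-epoch feature set (time-domain moments,
    Hjorth parameters, permutation entropy, fractal dimensions, Welch
    relative band powers and ratios, with smoothed-normalized variants),
    gradient-boosted multiclass staging with continued-training
    fine-tuning, leave-one-subject-out evaluation (confusion matrices,
    sensitivity/precision, Cohen's kappa, paired tests), mutual-information
    feature relevance, and Shapley-value model explanation. Includes a
    seedable multi-subject synthetic polysomnography generator with a
    configurable scalp-to-ear domain shift, and EDF/plain-text readers and
    writers, so the whole analysis is reproducible end to end without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
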