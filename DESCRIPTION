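Package: hradapt
Title: Heart-Rate-Driven Difficulty Adaptation for Exergames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-loop engine for heart-rate-driven dynamic difficulty
    adjustment in exergames aimed at children aged 5-7. Provides calibrated
    ingestion of 1 Hz wearable heart-rate streams (inter-device offset
    correction, outlier suppression, min-max scaling, 20-sample rolling
    window), the three published scenario difficulty controllers plus an
    architecture-test controller as pure state-transition functions, an
    event/user-property session model with lossless CSV/JSONL logging and
    deterministic replay, a first-order synthetic child-physiology simulator
    that closes the control loop under a crossover protocol, and the
    descriptive and paired t-test evaluation pipeline used to compare the
    adaptive and non-adaptive arms, including reproduction of inferential
    results directly from printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
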