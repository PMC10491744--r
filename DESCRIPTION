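Package: moodcpm
Title: Connectome-Based Predictive Modeling of Mood Symptom Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of clinical symptom
    severity from functional connectivity matrices: edge-wise feature
    selection at a p-value threshold, positive/negative network-strength
    summaries, linear prediction models, leave-one-out cross-validation,
    permutation inference, consensus-network interpretation (node degrees,
    hemispheric and macroscale-region edge classification), and transfer of
    frozen models to independent cohorts. Includes a synthetic-cohort
    generator with planted predictive networks for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
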