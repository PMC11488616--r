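Package: speechtags
Title: Part-of-Speech and Dependency Tag-Transition Features for Dementia
    Speech Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Featurizes part-of-speech and dependency annotated speech
    transcripts (CoNLL-U) into tag-frequency and adjacent-tag-transition
    feature vectors, labels visits as Alzheimer's disease or healthy control
    by ADNI-2 score rules, and classifies them with gradient-boosted trees
    under subject-grouped repeated random subsampling validation with
    averaged gain importances and group-wise feature-distribution summaries.
    Includes a first-order Markov synthetic-cohort generator so the full
    pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
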