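Package: mitopics
Title: Labeled Topic Models for Automated Fidelity Coding of
    Motivational-Interviewing Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised labeled topic models for predicting behavioral
    codes (Motivational Interviewing Skills Code, MISC) on psychotherapy
    session transcripts segmented into talk turns. Provides transcript
    corpus handling with n-gram phrase tokenization and multi-rater label
    fusion, collapsed Gibbs sampling for training with code, study and
    background topics, fold-in inference on held-out sessions,
    session-grouped k-fold cross-validation, and the psychometric
    evaluation stack used to score model codes against human raters:
    per-code ROC/AUC, pairwise Cohen's kappa, intraclass correlation on
    session code tallies, MI proficiency indices, and confusion-pair
    summaries. Includes a generative synthetic-corpus simulator with known
    ground truth and configurable imperfect raters for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
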