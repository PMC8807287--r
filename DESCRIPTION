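Package: vigimem
Title: Vigilance and Episodic Memory Decrement Analysis with Resampling
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trial-level scoring and inference for sustained-attention
    (vigilance) and episodic-memory experiments with unbalanced groups.
    Implements per-minute F1 signal-detection scoring with two-standard-
    deviation reaction-time trimming, normalized vigilance and memory
    decrement statistics, object-orientation misbinding false-alarm
    decomposition, bootstrap time-series divergence detection, bootstrap
    group tests for unbalanced samples, Jeffreys-Zellner-Siow Bayes
    factors, Spearman and partial rank correlations, PCA composite
    scores, and a synthetic cohort generator that emulates the
    data-generating structure of a two-group online cognitive study so
    that every pipeline stage is verifiable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
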