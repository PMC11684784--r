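Package: predecode
Title: Anticipatory Tone Decoding from Simulated MEG Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of anticipatory ("predictive") neural representations of upcoming
    pure tones in passive-listening MEG designs. Provides entropy-graded Markov
    tone-sequence generation, a synthetic sensor-space epoch generator with a
    controllable group-dependent pre-stimulus (de)activation effect, shrinkage
    linear discriminant decoding with temporal generalization and
    cross-condition decoding, neural prediction scores (regression slopes over
    entropy conditions or ordered-minus-random differences), and group-level
    inference: cluster-based permutation tests, JZS Bayes factors, equivalence
    (TOST) tests, Spearman correlations, logistic models with audiometric
    covariates, and trial-subsampling Bayes-factor curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
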