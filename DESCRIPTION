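Package: deltabind
Title: Differential Transcription-Factor Binding from Replicated Footprint Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-site transcription-factor binding scores (for example
    DNase-seq footprint shape scores) from two cell conditions into calibrated
    probabilities of condition-specific (differential) binding. Scores are
    standardized to rank space; the probability that a site is bound in the
    first condition is estimated from replicate reproducibility with an
    IDR-style two-cluster mixture on probit-transformed ranks, and the
    probability that the same site is significantly more weakly bound in the
    second condition is estimated with a windowed three-category mixture on
    rank differences. The product of the two gives the differential-binding
    score. Also provides the construction of high-confidence differential
    ChIP-seq ground truth from peak-caller statistics tables, baseline
    rankers, evaluation under extreme class imbalance (average precision,
    AUROC, precision at recall, permutation p-values), and a synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
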