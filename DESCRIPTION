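Package: altrsa
Title: Rational Speech Acts with Speaker Knowledge and Contextual Alternatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a Rational Speech Acts (RSA) model of scalar
    implicature in which the pragmatic listener jointly reasons about the
    speaker's partial knowledge of the world (how many of N objects the
    speaker has examined) and about which alternative utterances
    (quantifiers only, or quantifiers plus numerals under lower-bounded
    semantics) the speaker has available. Provides the literal listener,
    a knowledge-limited softmax speaker, a hypergeometric observation
    model, and an alternatives-marginalizing pragmatic listener, together
    with condition-table predictions and parameter sweeps. Also includes a
    synthetic-data generator for 2x2 (knowledgeability x numeral-exposure)
    rating experiments with pseudo-randomized trial orders, a contrast
    estimator of the two main effects and their interaction with
    participant-level bootstrap intervals, Monte-Carlo power analysis, and
    JSON/YAML/CSV interfaces with a thin command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
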