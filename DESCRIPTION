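Package: phosgram
Title: Grammar Inference for Kinase-Specific Phosphorylation Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a deterministic stochastic finite automaton (DSFA) from
    kinase substrate sequence windows with the Alergia state-merging
    algorithm, scores candidate serine/threonine windows by their generation
    probability, and localizes the phosphorylated residue via per-step
    emission probabilities. Includes a prefix tree acceptor with frequency
    counts, RPNI and genetic-algorithm DFA baselines, the full evaluation
    protocol (confusion metrics, ROC sweeps, asymmetric bootstrap, k-fold
    cross-validation, paired t-tests), a synthetic kinase-motif window
    generator, and a small command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
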