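Package: timnet
Title: Target Inhibition Network Modeling of Drug Combination Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the anticancer efficacy of multi-target inhibition
    from single-drug efficacies and drug-target binding profiles.
    Implements the TIMMA set-theoretic prediction rules (identical-set,
    maximization and minimization averaging), cancer-specific target-set
    selection by sequential forward floating search against the
    leave-one-out error, Bliss-independence synergy scoring of target and
    drug pairs, synthetic-lethality scoring of target pairs, and
    construction and export of target inhibition networks (parallel
    survival pathways).  Includes the PKIM baseline predictor with greedy
    selection, a simulation benchmark comparing the two, and processing of
    single and pairwise siRNA viability screens for experimental
    validation of predicted synergies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
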