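Package: homoplasr
Title: Quantifying Morphological Homoplasy on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify homoplasy in discrete morphological character
    matrices on rooted phylogenies. Implements Fitch/Hartigan maximum-parsimony
    ancestral-state reconstruction on possibly polytomous trees with ACCTRAN and
    DELTRAN most-parsimonious resolutions, per-character and ensemble
    consistency/retention/homoplasy indices with multi-tree averaging and a
    taxon-permutation null, a five-way categorization of character states
    (ancestral vs derived, synapomorphic, autapomorphic, homoplastic), a six-way
    pairwise classification of evolutionary mechanisms (inertia, parallelism,
    convergence, divergence, disparity), reversal counting, and stage/organ
    statistics including a developmental-hourglass regression. A coding front
    end discretizes numeric traits and RGB colors by Ward clustering with a
    cluster-validity vote, and a synthetic-data module simulates trees,
    Mk-model characters with a truth log, numeric traits and color tables so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
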