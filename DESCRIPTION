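Package: netpharm
Title: Network Pharmacology of Multi-Compound Herbal Formulas Against
    Disease Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for network-pharmacology analysis
    of multi-compound herbal formulas: ADME compound triage with a
    Tanimoto-coefficient drug-likeness score and the standard
    oral-bioavailability / Caco-2 / drug-likeness inclusion rule, typed
    compound-target / disease / merged / expanded network construction
    from confidence-scored protein-protein interaction data, a complete
    re-implementation of the MCODE molecular-complex detection algorithm
    (k-core based vertex weighting, seeded greedy complex prediction,
    haircut and fluff post-processing), hypergeometric over-representation
    analysis with Bonferroni correction (plain and EASE variants), and
    drug-disease biological-process overlap partitioned by disease
    etiology.  A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
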