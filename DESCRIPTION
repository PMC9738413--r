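Package: impnet
Title: Boolean Implication Networks and Multi-Omics Biomarker Screens for NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for anchored Boolean implication network analysis
    of multi-omics lung cancer cohorts. Expression matrices are discretized into
    ternary states using a normal range calibrated on housekeeping genes, and
    directed implication rules around an anchor gene (direct, two-hop, and
    mRNA-to-protein cross-layer) are scored with a one-tailed z statistic on rule
    precision against the consequent's marginal. Companion screens implement a
    three-criterion intermediate-gene filter (differential expression,
    CRISPR/RNAi dependency, prognostic stratification), Kaplan-Meier/log-rank
    survival machinery with backward-stepwise Cox risk scores and quadrant
    stratification, immune cell-score contrasts, drug-sensitivity gene calling
    with pan-sensitive/pan-resistant classification, and construction of up/down
    gene signatures for connectivity-map queries. A seeded synthetic cohort and
    cell-line panel generator with planted structure makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
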