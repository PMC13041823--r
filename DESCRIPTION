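Package: tptenet
Title: Transplacental Transfer Efficiency and Placental Co-Expression
    Network Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links per-compound transplacental transfer efficiency (TPTE)
    of per- and polyfluoroalkyl substances (PFAS) to the architecture of
    placental transcriptional mediation of perinatal outcomes.  Provides
    negative-binomial differential expression against exposure z-scores,
    transcriptome-wide quasi-Bayesian causal mediation (ACME/ADE), signed
    weighted co-expression networks with a parameter sweep and consensus
    hub extraction, edge-weighted network topology statistics (peak
    hub-to-mediator distances and maternal-fetal compartmentalization),
    and TPTE-scaling regressions, together with a synthetic-study
    generator that emulates the statistical structure these analyses
    assume and records ground truth for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    edgeR,
    igraph,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
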