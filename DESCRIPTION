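Package: carebench
Title: Benchmarking Economic and Social Performance of Community-Care
    Facilities with a Slacks-Based DEA Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Performance benchmarking of community-care facilities (CCFs)
    organised around the 4E framework (Economy, Efficiency, Effectiveness,
    Equity). Implements a delta-perturbed slacks-based measure (delta-SBM)
    data envelopment analysis model under variable returns to scale,
    slack-based projection onto the efficient frontier with per-indicator
    redundancy and shortfall diagnostics, perturbation sensitivity analysis,
    Spearman-based indicator screening, and a spatial stage regressing
    facility performance on regional GDP per capita by ordinary least
    squares and geographically weighted regression. A synthetic-data
    generator with planted frontier membership and a planted regression
    slope makes every stage runnable and testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
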