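Package: nidmsim
Title: Adaptive-Network Epidemic Games with Utility-Driven Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A seeded simulator for round-based social networking games played
    under an SIR-style epidemic. Sixty myopic utility-maximizing agents create,
    maintain and dissolve social ties under a reward system that pays for
    relations and triadic closure and penalizes infection, while a
    per-neighbor transmission process spreads disease over the evolving
    network. Includes constructive generators for low- and high-clustering
    baseline networks with matched degree, assortative versus random
    assignment of risk-aversion scores, a five-choice staircase
    risk-elicitation task, opportunity selection with similarity weighting,
    batch orchestration of the 2x2 experimental design, and exporters for
    network, decision and participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
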