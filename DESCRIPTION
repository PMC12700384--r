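Package: mirlink
Title: Multi-Evidence microRNA Prioritization and Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multi-tool microRNA target predictions with
    experimentally validated interaction records into per-pair evidence
    scores (P-, E-, C-scores) and per-miRNA panel-averaged T-scores, and
    carries the shortlisted miRNAs through downstream network analysis:
    pathway-target intersection, confidence-thresholded protein-protein
    interaction graphs with degree-based hub extraction, bipartite
    miRNA-gene networks, and hypergeometric over-representation analysis
    with Benjamini-Hochberg control. Ships a synthetic-data generator with
    planted ground truth so every pipeline stage can be benchmarked
    without querying external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
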