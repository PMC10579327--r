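Package: e3select
Title: Multi-Evidence Characterization and Prioritization of E3 Ligases for
    Targeted Protein Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles a confidence-scored catalog of human E3 ubiquitin
    ligases from multiple curated source lists, characterizes each ligase
    along the dimensions that matter for proteolysis-targeting chimera
    (PROTAC) development - chemical ligandability, tumor versus normal
    expression selectivity at bulk and single-cell resolution, aggregated
    protein-protein interactions, structure availability, functional
    essentiality, subcellular location, and interaction interfaces - and
    exposes a query engine for prioritizing candidate ligases against
    specific targets and cancer types. Ships a synthetic-data generator
    that emits a complete, internally consistent input bundle with a
    planted ground-truth manifest, so the full pipeline is testable
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
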