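Package: hierspread
Title: Hierarchical Spreading Processes on Multilayer Organizational Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of innovation spread through corporate
    hierarchies, modelled as a dose-memory elaboration of the SIR compartment
    model on two-layer and multi-layer networks. Provides generators for
    synthetic hierarchies (random geometric staff layer, fluid-communities
    partition, pluggable management-layer topologies), readers and fixture
    generators for empirical organizational networks (department-clique
    line organizations and hub-skewed co-working graphs), a fast micro-step
    dosage engine with hierarchical dose override and common-random-number
    replication, influential-spreader seed selection (degree, VoteRank,
    onion decomposition), and adoption, consensus-time and persistence
    metrics with ensemble aggregation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
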