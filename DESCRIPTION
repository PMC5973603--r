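Package: compoundgraph
Title: Complexity Management for Nested (Compound) Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Headless library and command-line tool for managing the visual
    complexity of large nested (compound) networks, such as biological pathway
    maps. Supports collapse and expand of compound nodes with consistent,
    order-independent meta-edge bookkeeping; hide and show of arbitrary
    sub-networks with a quadrant-scoring re-placement heuristic; incremental
    force-directed layout with a simulated-annealing temperature schedule; and
    fisheye-style space adjustment so that the user's mental map of the drawing
    survives each operation. Reads and writes nested GraphML and a JSON
    elements dialect, renders SVG with expand/collapse cues, and ships seeded
    generators for random compound graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
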