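Package: mlgraph
Title: Layered-Disjoint Multilayer Graphs: Creation, Modification and Layout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data structure and toolkit for layered-disjoint, node-colored
    multilayer graphs, in which every node belongs to exactly one named layer
    and edges may run within or between layers. Provides the standard
    create/read/update/delete operations on layers, nodes and attributed
    (possibly parallel) edges; transitivity-preserving node and layer deletion
    that inserts shortcut edges so reachability among surviving nodes is
    conserved; layer-based merging of two graphs with deduplication of shared
    nodes and edges; an invertible modification history with undo, so derived
    network views are documented and reproducible; deterministic scaled and
    seeded random layer-banded layouts in 2D and 3D; and serialization to a
    three-file CSV schema (nodes, edges, layers) and to the Cytoscape CX
    interchange format. Includes a demo graph, a seeded random multilayer
    graph generator and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
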