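# mlgraph

Layered-disjoint multilayer graphs for R: create, modify, merge, document
and lay out networks whose nodes are partitioned into named layers.

Integrating heterogeneous biomedical networks — pathways together with the
diseases, drugs and genes that annotate them — needs more than a monoplex
graph. `mlgraph` implements the node-colored multilayer model: a graph
*G = (V, E)* with a partition of *V* into layers *L₁ … Lₖ* (each node has
exactly one colour/layer), attributed edges both within and between layers,
and a directed or undirected interpretation. On top of the standard
create/read/update/delete surface it provides the operations such
integration work actually needs:

- **Transitivity-preserving deletion** — removing node *v* first inserts the
  shortcut *u → w* for every through-pair *u → v → w* (the neighbour clique,
  in the undirected case), so the reachability relation on the surviving
  nodes is exactly what it was. Works per node, and per layer for deleting a
  whole class of nodes.
- **Layer-based merging** — two graphs combine layer-by-layer (matched by
  name), with shared nodes and identical edges deduplicated and attribute
  unions taken (first argument wins conflicts).
- **Documented, undoable modification history** — every mutation is recorded
  as an invertible change record; `undo(g, k)` restores any earlier state
  exactly, and the history log documents how a network *view* was derived.
- **Layer-banded layouts** — deterministic *scaled* and seeded *random*
  layouts in 2D (one horizontal band per layer) and 3D (one plane per
  layer), overlap-free by construction; rendered to SVG/HTML.
- **Serialization** — a three-file CSV schema (nodes / edges / layers) with
  exact round-trip, and export to the Cytoscape CX interchange format.

## Worked example

```r
library(mlgraph)

g <- demo_graph()      # fixed 3-layer disease/drug/gene network
summary(g)
#> Multilayer graph 'demo' (undirected)
#> Layers: 3
#>   [1] disease: 2 node(s)
#>   [2] drug: 3 node(s)
#>   [3] gene: 3 node(s)
#> Nodes: 8
#> Edges: 8
#> History: 19 recorded modification(s)
```

Remove the `asthma` node while preserving every route that ran through it.
Its neighbours (`salbutamol`, `theophylline`, `IL4`) become mutually
adjacent; new shortcuts carry a `via` provenance attribute:

```r
g2 <- remove_node_transitive(g, "asthma")
get_edges(g2, between = "salbutamol")
#>   edge_id     source       target relation    via
#> 1       4 salbutamol        ADRB2  agonist   <NA>
#> 2       8 salbutamol theophylline     <NA>   <NA>
#> 3       9 salbutamol          IL4     <NA> asthma
```

The edge `salbutamol – theophylline` already existed, so no duplicate was
added; `salbutamol – IL4` is a new shortcut via the removed node. The
operation is one history step and inverts exactly:

```r
tail(get_history(g2)[, c("op_tag", "description")], 1)
#>                    op_tag                                           description
#> 20 remove_node_transitive removed node 'asthma' with transitive shortcut edges

graph_equal(undo(g2), g)
#> [1] TRUE
```

Deterministic scaled layout: layer *i* occupies the band
*y ∈ [i−0.9, i−0.1]* and its *n* nodes sit at *x = (j−0.5)/n*:

```r
head(layout_scaled(g, 2)$coords, 4)
#>          name layer_id         x   y
#> 1   influenza        1 0.2500000 0.5
#> 2      asthma        1 0.7500000 0.5
#> 3 oseltamivir        2 0.1666667 1.5
#> 4  salbutamol        2 0.5000000 1.5
```

Serialization and merging:

```r
export_csv(g, "demo")              # demo_layers.csv, demo_nodes.csv, demo_edges.csv
export_cx(g, "demo.cx", layout = layout_scaled(g, 3))
m <- merge_graphs(g, other_graph) # layer-based union, deduplicated
```

A command-line wrapper over the same functions ships at `inst/cli/mlgraph`
(`demo`, `info`, `merge`, `layout`, `export-cx`, `random` subcommands); run
it with no arguments for the flag grammar.

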