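---
title: "The layered-disjoint multilayer graph model in mlgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The layered-disjoint multilayer graph model in mlgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgraph)
```

## The model

Monoplex networks flatten heterogeneous biomedical data: a graph that mixes
diseases, drugs and genes as undifferentiated vertices loses the very
structure an integration pipeline needs. `mlgraph` implements a
*layered-disjoint, node-colored* multilayer graph: the vertex set is
partitioned into named layers (the node's "colour" — e.g. `disease`, `drug`,
`gene`), every node belongs to exactly one layer, and attributed edges may
run within a layer (intra-layer) or between layers (inter-layer). The graph
as a whole is directed or undirected; edges carry scalar attribute maps and
parallel edges between the same pair are allowed precisely when their
attribute maps differ, which gives edges a well-defined identity
(endpoints + attributes) that the merge and serialization machinery relies
on. Self-loops are rejected: they have no meaning under transitivity-
preserving deletion and nothing in the model needs them.

Identity conventions, chosen once and used everywhere:

* **Node identity is the name string**, unique across the whole graph, not
  per layer. Merging and the CSV schema index nodes by name; per-layer
  duplicates would make both ambiguous.
* **Layer names are unique case-insensitively**; lookups are forgiving
  (`"Gene"` finds `"gene"`) but the stored spelling is preserved, so output
  is deterministic.
* **Layer ids are always the contiguous sequence `1..k`** in assignment
  order; removing a layer compacts the ids of the survivors. Layout banding
  and the CSV layer file both assume this contiguity.
* **Attribute values are scalars** (string, double, logical). Numbers are
  normalised to double at entry so a graph that has been written to CSV or
  CX and read back compares equal. Nested attribute structures are out of
  scope: they do not survive flat CSV.

## Transitivity-preserving deletion

Deleting a node `v` normally severs every route that passed through it.
`remove_node_transitive()` (and `remove_node(trans = TRUE)`,
`remove_layer(trans = TRUE)`) first inserts *shortcut* edges:

* **directed** — for every in-neighbour `u` and out-neighbour `w` of `v`
  with `u != w`, the edge `u -> w` is planned unless some `u -> w` edge
  already exists;
* **undirected** — every pair of distinct neighbours of `v` is connected
  unless already adjacent, i.e. the neighbourhood of `v` closes into a
  clique.

One hop suffices: every path of length two through `v` is replaced by its
shortcut, longer paths survive segment by segment, and because the argument
applies again to the next removal, *sequential* removals (e.g. deleting a
whole layer node by node) preserve reachability inductively. No transitive
closure is ever computed by the implementation — the test suite instead
checks the guarantee against an independent brute-force closure oracle
(boolean adjacency-matrix squaring) over seeded random graphs, directed and
undirected.

Planned shortcuts carry a single provenance attribute `via = <removed
node>`. We deliberately do not attempt to combine the two parent edges'
attribute maps: there is no principled algebra for, say, a `weight` from one
edge and a `relation` from the other, and lossless provenance keeps the
operation deterministic and auditable. A shortcut is suppressed whenever
*any* edge with the same endpoints already exists, regardless of its
attributes — a parallel `via` edge would add nothing to reachability, which
is the property the operation exists to protect.

```{r transitive}
g <- mlgraph("path", directed = TRUE)
g <- add_layer(g, "L1"); g <- add_layer(g, "L2"); g <- add_layer(g, "L3")
g <- add_node(g, "a", "L1"); g <- add_node(g, "v", "L2"); g <- add_node(g, "b", "L3")
g <- add_edge(g, "a", "v"); g <- add_edge(g, "v", "b")
get_edges(remove_node_transitive(g, "v"))
```

## Layer-based merging

`merge_graphs(g1, g2)` integrates two graphs of equal directedness. Layers
are matched by case-insensitive *name* — ids are graph-local and meaningless
across graphs. The result takes `g1`'s layers, appends `g2`'s unmatched
layers, and recompacts ids. Nodes are matched by name: a shared node must
sit on the same layer in both graphs (a mismatch raises a layer-conflict
error rather than silently re-colouring a node) and receives the union of
both attribute maps, with **the first argument winning conflicts**. This
precedence is a documented design choice where several were defensible;
first-argument-wins is deterministic, and order sensitivity is part of the
tested contract. Edges of `g2` are appended unless an edge with identical
endpoints and attributes already exists, so shared content is never
replicated. Merging more than two graphs is done by folding.

The merged graph is a new *view origin*: it starts a fresh history whose
first record is the merge itself, marked non-invertible — `undo()` cannot
cross back into the parents.

## History and views

Every mutating operation — and only mutating operations — appends one
`ChangeRecord`: sequence number, UTC ISO-8601 timestamp, operation tag, a
human-readable description, and a full snapshot of the pre-operation state
(layers, nodes, edges, edge-id counter). Full snapshots rather than
operation parameters were chosen deliberately: compound operations
(transitive removal, layer removal) invert exactly without re-deriving
plans, and the graphs this package targets are desk-scale, so correctness
wins over memory. Undo is linear — a stack, no redo, no branching; a *view*
is simply a graph copy plus its history log (`get_history()`,
`export_history()`), which documents every step that produced the current
network from the original and makes a derived network reproducible by
replay. History is runtime-only: the CSV schema has no slot for it, so
`export_history()` writes the provenance separately when it needs to travel.

## Layouts

Layouts place each layer in its own region so the layer structure is visible
at a glance; both variants guarantee vertices never coincide.

* **Bands and planes.** In 2D, layer `i` of `k` occupies the horizontal band
  `y ∈ [i-1+m, i-m]` with margin `m = 0.1` (unit-height bands, so bands of
  distinct layers are disjoint and stack monotonically by id). In 3D, layer
  `i` is the plane `z = i`. The concrete geometry is this package's own
  convention; the model only demands that co-layered nodes share a
  coordinate range.
* **Scaled** (`layout_scaled()`): layer `i`'s `n` nodes sit at
  `x = (j-0.5)/n`, `j = 1..n` in insertion order, on the band midline (2D),
  or on a centred square grid of side `ceiling(sqrt(n))` with unit spacing
  (3D). Insertion order was preferred to alphabetical so a rename cannot
  reshuffle a layout. Pure arithmetic — repeated calls are bit-identical.
* **Random** (`layout_random()`): same bands/planes; within-band positions
  are drawn uniformly and resampled until every within-layer pair is at
  least `epsilon = 0.05` apart (at most 1000 resamples per layer, after
  which a capacity error advises the scaled layout — an explicit failure is
  better than silent overlap). The generator takes an explicit seed
  (default 42) and leaves the session RNG untouched; reproducibility is part
  of the contract even though "random" is in the name.

`render_layout()` is purely presentational — it draws coordinates computed
upstream and computes none itself. 2D layouts are written as self-contained
SVG (bands shaded, nodes coloured by layer, edges drawn); 3D as a
self-contained HTML file embedding an oblique-projection SVG scene, one
translucent plane per layer. Interactive rotation/zoom engines are out of
scope.

## Serialization

**CSV** (`export_csv()` / `import_csv()`) uses three files —
`<base>_layers.csv` (`id,name`), `<base>_nodes.csv` (`name,layer,` + the
union of node attribute keys), `<base>_edges.csv` (`source,target,` + the
union of edge attribute keys) — RFC 4180 quoting, UTF-8, header always
present, rows in insertion order, missing attribute = empty cell. Exact
column names and the suffix convention are this package's dialect. Because
CSV is untyped, import re-types each cell (`TRUE`/`FALSE` → logical,
numeric-parsable → double, else string); consequently a *string* that spells
a number or a bare `TRUE` does not survive a round trip as a string, and
empty-string attribute values are rejected at entry since an empty cell
already means "absent". The keys `name`, `layer`, `source`, `target`, `id`
are reserved for the schema's fixed columns. Directedness has no slot in
the three files and is a required import parameter. `import(export(g))` is
deep-equal to `g` up to history.

**CX** (`export_cx()`) writes the JSON aspect array used by Cytoscape and
NDEx: `metaData`, `networkAttributes` (name, directedness), `nodes`,
`edges` (ids 0-based in insertion order), `nodeAttributes` (exactly one
`layer` entry per node plus user attributes, each typed with a `d` field
where non-string), `edgeAttributes`, an optional `cartesianLayout` taken
from a layout object, and `status`. Export-only, matching the exchange
direction the model needs; `validate_cx()` checks internal consistency
(counts, endpoint references, layer coverage) and is used by the test suite.
Cytoscape visual-style aspects and NDEx server transfer are out of scope.

## The fixtures: what they emulate and what they do not

`demo_graph()` is a fixed three-layer undirected disease/drug/gene network
(8 nodes, 8 edges, intra- and inter-layer, some attributed) — the canonical
worked example. `random_multilayer(n_layers, nodes_per_layer, edge_prob,
directed, seed)` is an Erdős–Rényi-style generator stratified into equal
layers: every node pair, within and across layers, gains an edge
independently with probability `edge_prob`. The property suites run it at 3
layers × 10 nodes with `edge_prob = 0.15` (directed and undirected), a
density at which removals routinely cut real routes — the regime that
actually exercises transitive deletion — while closures stay instant; the
undo and serialization sweeps use 3 × 5 and 1–4 × 5 graphs over ~100 seeds
each so the full suite runs in about a minute on one CPU.

What the generator does *not* emulate: real pathway-derived networks have
hubs and heavy-tailed degrees, correlated inter-layer structure, and rich
attribute maps; the generator's edges are independent and attribute-free.
Passing tests therefore demonstrate the *algorithmic invariants* —
reachability conservation, undo exactness, merge laws, round-trip fidelity,
layout geometry — not statistical realism of the inputs. The invariants are
input-distribution-free by construction, which is why property tests over a
simple generator are the right instrument.

## Numerical and degenerate-input choices

* Attribute equality is key-set + value equality with numbers compared
  exactly as doubles; CSV writes numbers with `as.character()` precision
  (~15 significant digits), ample for round-tripping values produced here.
* Removing the last layer is allowed and yields an empty graph; an empty
  layer gets a band with no points; a zero-layer graph cannot be laid out
  (validation error).
* `remove_edge()` with several parallel matches and `multi = FALSE` is an
  ambiguity error, never an arbitrary pick.
* Ties in the random layout are broken by resampling, never by nudging;
  determinism in the scaled layout comes from avoiding RNG entirely.

## Limitations

Edge-colored multilayer semantics (node replication across layers),
hypergraphs, multi-layer node membership, fuzzy cross-graph node matching,
redo/branching histories, force-directed layouts and CX *import* are all
out of scope. The container is an R list with copy-on-modify value
semantics — ideal for undo and reproducibility, not for graphs with
millions of edges.
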