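test_that("graph construction round-trips its fields and validates the name", {
  g <- mlgraph("demo", directed = FALSE)
  expect_s3_class(g, "mlgraph")
  expect_equal(nrow(get_layers(g)), 0)
  expect_equal(nrow(get_nodes(g)), 0)
  expect_equal(nrow(get_edges(g)), 0)
  expect_equal(nrow(get_history(g)), 0)
  expect_true(is_directed(mlgraph("g", directed = TRUE)))
  expect_false(is_directed(g))
  expect_error(mlgraph(""), class = "mlgraph_validation_error")
  expect_error(mlgraph("g", directed = NA), class = "mlgraph_validation_error")
})

test_that("layers get sequential ids and case-insensitive unique names", {
  g <- mlgraph("g")
  g <- add_layer(g, "gene")
  expect_equal(get_layers(g), data.frame(id = 1L, name = "gene"))
  g <- add_layer(g, "drug")
  g <- add_layer(g, "disease")
  expect_equal(get_layers(g)$id, 1:3)
  expect_error(add_layer(g, "Gene"), class = "mlgraph_duplicate_error")
  # lookups are case-insensitive but stored spelling is preserved
  g <- add_node(g, "TP53", "GENE")
  expect_equal(get_layer_of(g, "TP53"), "gene")
})

test_that("nodes are bound to one existing layer and unique graph-wide", {
  g <- add_layer(add_layer(mlgraph("g"), "gene"), "drug")
  g <- add_node(g, "TP53", "gene", attributes = list(type = "tsg"))
  expect_equal(get_layer_of(g, "TP53"), "gene")
  expect_equal(get_node_attributes(g, "TP53"), list(type = "tsg"))
  expect_error(add_node(g, "TP53", "drug"), class = "mlgraph_duplicate_error")
  expect_error(add_node(g, "BRCA1", "protein"), class = "mlgraph_not_found_error")
  expect_error(get_layer_of(g, "nope"), class = "mlgraph_not_found_error")
})

test_that("attribute validation rejects malformed maps", {
  g <- add_layer(mlgraph("g"), "gene")
  expect_error(add_node(g, "x", "gene", list(1, 2)),
               class = "mlgraph_validation_error")
  expect_error(add_node(g, "x", "gene", list(a = NULL)),
               class = "mlgraph_validation_error")
  expect_error(add_node(g, "x", "gene", list(a = c(1, 2))),
               class = "mlgraph_validation_error")
  expect_error(add_node(g, "x", "gene", list(a = NA)),
               class = "mlgraph_validation_error")
  expect_error(add_node(g, "x", "gene", list(a = "")),
               class = "mlgraph_validation_error")
  expect_error(add_node(g, "x", "gene", list(layer = "y")),
               class = "mlgraph_validation_error")
  # integers are normalised to double so serialization round-trips exactly
  g <- add_node(g, "x", "gene", list(n = 5L))
  expect_identical(get_node_attributes(g, "x")$n, 5)
})

test_that("edges: intra-layer legal, parallel iff attributes differ, no self-loops", {
  g <- add_layer(mlgraph("g"), "gene")
  g <- add_node(g, "a", "gene")
  g <- add_node(g, "b", "gene")
  g <- add_edge(g, "a", "b")                       # intra-layer edge accepted
  expect_equal(nrow(get_edges(g)), 1)
  g <- add_edge(g, "a", "b", list(w = 2))          # parallel, different attrs
  expect_equal(nrow(get_edges(g)), 2)
  expect_error(add_edge(g, "a", "b", list(w = 2)), # exact duplicate
               class = "mlgraph_duplicate_error")
  expect_error(add_edge(g, "a", "a"), class = "mlgraph_validation_error")
  expect_error(add_edge(g, "a", "zzz"), class = "mlgraph_not_found_error")
})

test_that("undirected graphs treat (s,t) and (t,s) as the same edge", {
  g <- add_layer(mlgraph("g"), "L")
  g <- add_node(g, "a", "L"); g <- add_node(g, "b", "L")
  g <- add_edge(g, "a", "b")
  expect_error(add_edge(g, "b", "a"), class = "mlgraph_duplicate_error")
  expect_equal(get_edges(g, between = "a"), get_edges(g, between = "b"))
  # a directed graph accepts the reverse orientation as a distinct edge
  d <- add_layer(mlgraph("d", directed = TRUE), "L")
  d <- add_node(d, "a", "L"); d <- add_node(d, "b", "L")
  d <- add_edge(d, "a", "b")
  d <- add_edge(d, "b", "a")
  expect_equal(nrow(get_edges(d)), 2)
})

test_that("remove_edge handles unique, filtered, multi and ambiguous matches", {
  g <- add_layer(mlgraph("g"), "L")
  g <- add_node(g, "a", "L"); g <- add_node(g, "b", "L")
  g1 <- add_edge(g, "a", "b")
  expect_equal(nrow(get_edges(remove_edge(g1, "a", "b"))), 0)
  g2 <- add_edge(g1, "a", "b", list(w = 1))
  expect_error(remove_edge(g2, "a", "b"), class = "mlgraph_ambiguous_error")
  expect_equal(nrow(get_edges(remove_edge(g2, "a", "b", multi = TRUE))), 0)
  expect_equal(nrow(get_edges(remove_edge(g2, "a", "b", attributes = list(w = 1)))), 1)
  expect_error(remove_edge(g2, "a", "b", attributes = list(w = 9)),
               class = "mlgraph_not_found_error")
})

test_that("remove_node drops the node and its incident edges", {
  g <- path_graph(directed = FALSE)
  g2 <- remove_node(g, "v")
  expect_false("v" %in% get_nodes(g2)$name)
  expect_equal(nrow(get_edges(g2)), 0)
  # isolated node with trans = TRUE: edge set unchanged
  g3 <- add_node(g, "iso", "L2")
  g4 <- remove_node(g3, "iso", trans = TRUE)
  expect_equal(get_edges(g4), get_edges(g))
  expect_error(remove_node(g, "zzz"), class = "mlgraph_not_found_error")
})

test_that("remove_layer compacts ids and honours the trans flag", {
  # empty middle layer: node set unchanged, ids compact
  g <- mlgraph("g")
  for (l in c("A", "B", "C")) g <- add_layer(g, l)
  g <- add_node(g, "a", "A"); g <- add_node(g, "c", "C")
  g2 <- remove_layer(g, "B")
  expect_equal(get_layers(g2), data.frame(id = 1:2, name = c("A", "C")))
  expect_equal(get_nodes(g2)$name, c("a", "c"))
  expect_equal(get_layer_of(g2, "c"), "C")
  validate_graph(g2)

  # path a(L1) -> v(L2) -> b(L3): deleting L2 keeps the a -> b route iff trans
  p <- path_graph(directed = TRUE)
  pt <- remove_layer(p, "L2", trans = TRUE)
  et <- get_edges(pt)
  expect_equal(nrow(et), 1)
  expect_equal(et$source, "a"); expect_equal(et$target, "b")
  expect_equal(et$via, "v")
  pf <- remove_layer(p, "L2", trans = FALSE)
  expect_equal(nrow(get_edges(pf)), 0)
  expect_error(remove_layer(p, "nope"), class = "mlgraph_not_found_error")
})

test_that("removing the last layer yields an empty graph", {
  g <- add_layer(mlgraph("g"), "only")
  g <- add_node(g, "x", "only")
  g2 <- remove_layer(g, "only")
  expect_equal(nrow(get_layers(g2)), 0)
  expect_equal(nrow(get_nodes(g2)), 0)
})

test_that("getter filters follow their definitions", {
  g <- demo_graph()
  genes <- get_nodes(g, "gene")
  expect_setequal(genes$name, c("IFNG", "IL4", "ADRB2"))
  expect_true(all(genes$layer == "gene"))

  dg <- get_edges(g, between = c("drug", "gene"))
  for (i in seq_len(nrow(dg))) {
    expect_setequal(c(get_layer_of(g, dg$source[i]), get_layer_of(g, dg$target[i])),
                    c("drug", "gene"))
  }
  expect_equal(get_edges(g, between = c("drug", "gene")),
               get_edges(g, between = c("gene", "drug")))

  inc <- get_edges(g, between = "asthma")
  expect_true(all(inc$source == "asthma" | inc$target == "asthma"))

  expect_equal(nrow(get_edges(mlgraph("empty"))), 0)
  expect_error(get_edges(g, between = c("drug", "nope")),
               class = "mlgraph_not_found_error")
  expect_error(get_nodes(g, "nope"), class = "mlgraph_not_found_error")
})

test_that("queries are pure: the graph is bit-identical before and after", {
  g <- demo_graph()
  before <- unserialize(serialize(g, NULL))
  invisible(get_layers(g)); invisible(get_nodes(g, "drug"))
  invisible(get_edges(g, between = c("drug", "disease")))
  invisible(get_node_attributes(g, "asthma")); invisible(get_layer_of(g, "IL4"))
  invisible(get_history(g))
  expect_identical(g, before)
})

test_that("summary reports per-layer counts and directedness", {
  lines <- capture.output(res <- summary(demo_graph()))
  expect_match(lines[1], "undirected")
  expect_match(paste(lines, collapse = "\n"), "\\[2\\] drug: 3 node")
  expect_match(paste(lines, collapse = "\n"), "Edges: 8")
})

test_that("structural invariants hold across random mutation sequences", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- random_multilayer(3, 4, 0.25, directed = seed %% 2 == 0, seed = seed)
    g <- apply_random_ops(g, 15, validate = TRUE)
    expect_true(validate_graph(g))
  }
})
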