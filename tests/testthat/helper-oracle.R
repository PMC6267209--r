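# Independent reachability oracle: boolean transitive closure by repeated
# squaring of the adjacency matrix, built from the public getters only. This
# is deliberately not the one-hop shortcut algorithm it is used to check.
reach_matrix <- function(g) {
  nodes <- get_nodes(g)$name
  n <- length(nodes)
  M <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  ed <- get_edges(g)
  for (i in seq_len(nrow(ed))) {
    M[ed$source[i], ed$target[i]] <- TRUE
    if (!is_directed(g)) M[ed$target[i], ed$source[i]] <- TRUE
  }
  R <- M | diag(n) > 0
  repeat {
    R2 <- ((R %*% R) > 0) | R
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# TRUE iff removing `node` (with transitive shortcuts) conserved reachability
# among the survivors.
reachability_conserved <- function(g, node) {
  before <- reach_matrix(g)
  g2 <- remove_node_transitive(g, node)
  after <- reach_matrix(g2)
  surv <- rownames(after)
  identical(after, before[surv, surv, drop = FALSE])
}

expect_graph_equal <- function(object, expected, include_ids = TRUE) {
  expect_true(graph_equal(object, expected, include_ids = include_ids))
}

# A small fixed 3-layer path fixture: a (L1) -> v (L2) -> b (L3).
path_graph <- function(directed = TRUE) {
  g <- mlgraph("path", directed = directed)
  g <- add_layer(g, "L1"); g <- add_layer(g, "L2"); g <- add_layer(g, "L3")
  g <- add_node(g, "a", "L1"); g <- add_node(g, "v", "L2")
  g <- add_node(g, "b", "L3")
  g <- add_edge(g, "a", "v")
  add_edge(g, "v", "b")
}

# Apply k random valid mutations drawn from the full mutating surface,
# returning the final graph. Used by the undo and invariant property tests.
apply_random_ops <- function(g, k, validate = FALSE) {
  for (step in seq_len(k)) {
    repeat {
      op <- sample(c("add_layer", "add_node", "add_edge", "remove_node",
                     "remove_node_trans", "remove_edge", "remove_layer"), 1,
                   prob = c(0.1, 0.25, 0.3, 0.1, 0.1, 0.1, 0.05))
      layers <- get_layers(g)$name
      nodes <- get_nodes(g)$name
      edges <- get_edges(g)
      done <- switch(op,
        add_layer = {
          g <- add_layer(g, sprintf("extra_%d_%d", step, sample.int(1e6, 1)))
          TRUE
        },
        add_node = if (length(layers)) {
          g <- add_node(g, sprintf("node_%d_%d", step, sample.int(1e6, 1)),
                        sample(layers, 1))
          TRUE
        } else FALSE,
        add_edge = if (length(nodes) >= 2) {
          ends <- sample(nodes, 2)
          if (!any(vapply(seq_len(nrow(edges)), function(i) {
                (edges$source[i] == ends[1] && edges$target[i] == ends[2]) ||
                (!is_directed(g) && edges$source[i] == ends[2] &&
                   edges$target[i] == ends[1])
              }, logical(1)))) {
            g <- add_edge(g, ends[1], ends[2])
            TRUE
          } else FALSE
        } else FALSE,
        remove_node = if (length(nodes)) {
          g <- remove_node(g, sample(nodes, 1))
          TRUE
        } else FALSE,
        remove_node_trans = if (length(nodes)) {
          g <- remove_node_transitive(g, sample(nodes, 1))
          TRUE
        } else FALSE,
        remove_edge = if (nrow(edges)) {
          i <- sample.int(nrow(edges), 1)
          g <- remove_edge(g, edges$source[i], edges$target[i], multi = TRUE)
          TRUE
        } else FALSE,
        remove_layer = if (length(layers)) {
          g <- remove_layer(g, sample(layers, 1), trans = sample(c(TRUE, FALSE), 1))
          TRUE
        } else FALSE)
      if (isTRUE(done)) break
    }
    if (validate) validate_graph(g)
  }
  g
}
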