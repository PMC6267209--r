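# Transitivity-preserving deletion. Removing a node v normally severs every
# route that passed through it; planning the one-hop shortcuts u->w for each
# through-pair (u->v, v->w) before removal keeps the reachability relation on
# the surviving nodes exactly what it was. One hop suffices: every
# length-2 path through v is replaced, so longer paths survive segment by
# segment, and sequential removals preserve reachability inductively.

#' Plan the transitive shortcut edges for a node removal
#'
#' Computes, without mutating the graph, the shortcut edges needed so that
#' removing `node_name` leaves reachability among the remaining nodes
#' unchanged. Directed: for every in-neighbour `u` and out-neighbour `w` of
#' the node with `u != w`, an edge `u -> w` is planned unless some edge
#' `u -> w` already exists. Undirected: every unordered pair of distinct
#' neighbours is connected unless already adjacent (the neighbourhood becomes
#' a clique). Planned edges carry a single provenance attribute
#' `via = <removed node>`; self-loops are never planned.
#'
#' @param g An `mlgraph`.
#' @param node_name Name of an existing node.
#' @return An object of class `transitive_plan`: a list with `removed_node`,
#'   `new_edges` (each a list with `source`, `target`, `attributes`) and
#'   `dropped_edges` (ids of the incident edges the removal will delete).
#' @seealso [remove_node_transitive()] which applies the plan.
#' @export
plan_transitive_edges <- function(g, node_name) {
  assert_mlgraph(g)
  check_string(node_name, "node name")
  if (!node_exists(g, node_name)) {
    err_not_found(sprintf("node '%s' does not exist", node_name))
  }
  v <- node_name
  incident <- Filter(function(e) e$source == v || e$target == v, g$edges)
  dropped <- vapply(incident, function(e) as.integer(e$edge_id), integer(1))

  pairs <- list()
  if (g$directed) {
    ins <- unique(vapply(Filter(function(e) e$target == v, incident),
                         `[[`, character(1), "source"))
    outs <- unique(vapply(Filter(function(e) e$source == v, incident),
                          `[[`, character(1), "target"))
    for (u in ins) for (w in outs) {
      if (u != w && u != v && w != v) pairs[[length(pairs) + 1L]] <- c(u, w)
    }
  } else {
    nbrs <- unique(unlist(lapply(incident, function(e) c(e$source, e$target))))
    nbrs <- setdiff(nbrs, v)
    if (length(nbrs) >= 2L) {
      cmb <- utils::combn(nbrs, 2L)
      for (j in seq_len(ncol(cmb))) pairs[[j]] <- cmb[, j]
    }
  }

  new_edges <- list()
  for (p in pairs) {
    if (!edge_exists(g, p[1L], p[2L])) {
      new_edges[[length(new_edges) + 1L]] <-
        list(source = p[1L], target = p[2L], attributes = list(via = v))
    }
  }
  structure(list(removed_node = v, new_edges = new_edges,
                 dropped_edges = dropped),
            class = "transitive_plan")
}

#' @export
print.transitive_plan <- function(x, ...) {
  cat(sprintf("transitive plan for removing '%s': %d shortcut edge(s), %d incident edge(s) dropped\n",
              x$removed_node, length(x$new_edges), length(x$dropped_edges)))
  for (e in x$new_edges) cat(sprintf("  + %s -> %s\n", e$source, e$target))
  invisible(x)
}

#' Remove a node while preserving reachability
#'
#' Applies the plan from [plan_transitive_edges()], then removes the node and
#' its incident edges, as one atomic, singly-undoable history step.
#' Equivalent to `remove_node(g, node_name, trans = TRUE)`.
#'
#' @param g An `mlgraph`.
#' @param node_name Name of an existing node.
#' @return The updated graph.
#' @export
remove_node_transitive <- function(g, node_name) {
  remove_node(g, node_name, trans = TRUE)
}
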