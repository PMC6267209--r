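#' Create an empty multilayer graph
#'
#' Constructs a layered-disjoint, node-colored multilayer graph: the vertex
#' set is partitioned into named layers and every node belongs to exactly one
#' layer. Edges may connect nodes within a layer (intra-layer) or across
#' layers (inter-layer), and the graph as a whole is either directed or
#' undirected.
#'
#' All mutating operations (`add_layer()`, `add_node()`, `add_edge()`,
#' `remove_*()`, ...) return the updated graph and append an invertible
#' [ChangeRecord][get_history] to its history; callers must treat the returned
#' value as the current graph.
#'
#' @param name Graph name, a non-empty string.
#' @param directed Logical; `FALSE` (default) for an undirected graph.
#' @return An object of class `mlgraph` with zero layers, nodes and edges and
#'   an empty history.
#' @examples
#' g <- mlgraph("demo", directed = FALSE)
#' g <- add_layer(g, "gene")
#' g <- add_node(g, "TP53", "gene", attributes = list(type = "tumour suppressor"))
#' @export
mlgraph <- function(name, directed = FALSE) {
  check_string(name, "graph name")
  if (!is.logical(directed) || length(directed) != 1L || is.na(directed)) {
    err_validation("'directed' must be TRUE or FALSE")
  }
  structure(
    list(
      name = name,
      directed = directed,
      layers = data.frame(id = integer(), name = character(),
                          stringsAsFactors = FALSE),
      nodes = list(),
      edges = list(),
      next_edge_id = 1L,
      history = list()
    ),
    class = "mlgraph"
  )
}

#' Test whether an object is a multilayer graph
#' @param x Any object.
#' @return `TRUE` if `x` inherits from class `mlgraph`.
#' @export
is_mlgraph <- function(x) inherits(x, "mlgraph")

#' Is the graph directed?
#' @param g An `mlgraph`.
#' @return `TRUE` for a directed graph, `FALSE` for an undirected one.
#' @export
is_directed <- function(g) {
  assert_mlgraph(g)
  g$directed
}

# ---- internal helpers -------------------------------------------------------

assert_mlgraph <- function(g) {
  if (!is_mlgraph(g)) err_validation("expected an 'mlgraph' object")
  invisible(g)
}

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    err_validation(sprintf("%s must be a non-empty string", what))
  }
  invisible(x)
}

# Layer lookup is case-insensitive; stored spelling is preserved.
layer_index <- function(g, layer_name) {
  match(tolower(layer_name), tolower(g$layers$name))
}

layer_name_of_id <- function(g, id) {
  g$layers$name[match(id, g$layers$id)]
}

node_exists <- function(g, node_name) {
  !is.null(g$nodes[[node_name]])
}

RESERVED_ATTR_KEYS <- c("name", "layer", "source", "target", "id")

# Attribute maps are named lists of length-1 scalars: string / double /
# logical. Numbers are normalised to double so CSV and CX round-trips are
# type-exact; empty strings are rejected because the CSV dialect encodes a
# missing attribute as an empty cell.
validate_attrs <- function(attributes) {
  if (is.null(attributes)) return(structure(list(), names = character()))
  if (!is.list(attributes)) err_validation("attributes must be a named list")
  if (length(attributes) == 0L) return(structure(list(), names = character()))
  keys <- names(attributes)
  if (is.null(keys) || any(is.na(keys)) || any(!nzchar(keys))) {
    err_validation("every attribute must have a non-empty name")
  }
  if (anyDuplicated(keys)) err_validation("duplicate attribute names")
  bad <- intersect(keys, RESERVED_ATTR_KEYS)
  if (length(bad)) {
    err_validation(sprintf("attribute name(s) %s are reserved",
                           paste(sQuote(bad), collapse = ", ")))
  }
  out <- lapply(attributes, function(v) {
    if (length(v) != 1L || !is.atomic(v) || is.na(v)) {
      err_validation("attribute values must be non-missing scalars")
    }
    if (is.numeric(v)) return(as.numeric(v))
    if (is.logical(v)) return(v)
    if (is.character(v)) {
      if (!nzchar(v)) err_validation("attribute string values must be non-empty")
      return(v)
    }
    err_validation("attribute values must be string, number or logical")
  })
  names(out) <- keys
  out
}

# Exact attribute-map equality: same key set, each value identical
# (numbers compared exactly as doubles, types must agree).
attrs_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  ka <- sort(names(a)); kb <- sort(names(b))
  if (!identical(ka, kb)) return(FALSE)
  for (k in ka) if (!identical(a[[k]], b[[k]])) return(FALSE)
  TRUE
}

# Endpoint match; orientation-insensitive when the graph is undirected.
same_endpoints <- function(g, e, source, target) {
  if (e$source == source && e$target == target) return(TRUE)
  if (!g$directed && e$source == target && e$target == source) return(TRUE)
  FALSE
}

edge_exists <- function(g, source, target) {
  for (e in g$edges) if (same_endpoints(g, e, source, target)) return(TRUE)
  FALSE
}

edge_dup_exists <- function(g, source, target, attributes) {
  for (e in g$edges) {
    if (same_endpoints(g, e, source, target) &&
        attrs_equal(e$attributes, attributes)) return(TRUE)
  }
  FALSE
}

# The undoable portion of the graph state (everything except the history).
core_state <- function(g) {
  g[c("name", "directed", "layers", "nodes", "edges", "next_edge_id")]
}

restore_core <- function(g, snapshot) {
  g[names(snapshot)] <- snapshot
  g
}

# ---- layers -----------------------------------------------------------------

#' Add a layer to a multilayer graph
#'
#' Layer names are unique under case-insensitive comparison; the stored
#' spelling is preserved. The new layer receives id `k + 1` where `k` is the
#' current layer count.
#'
#' @param g An `mlgraph`.
#' @param layer_name Non-empty layer name.
#' @return The updated graph.
#' @export
add_layer <- function(g, layer_name) {
  assert_mlgraph(g)
  check_string(layer_name, "layer name")
  if (!is.na(layer_index(g, layer_name))) {
    err_duplicate(sprintf("layer '%s' already exists (layer names are case-insensitive)",
                          layer_name))
  }
  snap <- core_state(g)
  g <- add_layer_impl(g, layer_name)
  push_record(g, "add_layer",
              sprintf("added layer '%s' (id %d)", layer_name, nrow(g$layers)),
              snap)
}

add_layer_impl <- function(g, layer_name) {
  g$layers <- rbind(g$layers,
                    data.frame(id = nrow(g$layers) + 1L, name = layer_name,
                               stringsAsFactors = FALSE))
  rownames(g$layers) <- NULL
  g
}

#' Remove a layer, its nodes and their edges
#'
#' Every node on the layer is removed in insertion order via the node-removal
#' machinery; with `trans = TRUE` each removal first inserts the transitive
#' shortcut edges that preserve reachability among the surviving nodes (see
#' [plan_transitive_edges()]). Remaining layer ids are compacted to
#' `1..k-1`, preserving relative order. The whole operation is one atomic,
#' singly-undoable history step.
#'
#' @param g An `mlgraph`.
#' @param layer_name Name of an existing layer (case-insensitive).
#' @param trans Logical; insert transitive shortcut edges before each node
#'   removal.
#' @return The updated graph.
#' @export
remove_layer <- function(g, layer_name, trans = FALSE) {
  assert_mlgraph(g)
  check_string(layer_name, "layer name")
  idx <- layer_index(g, layer_name)
  if (is.na(idx)) err_not_found(sprintf("layer '%s' does not exist", layer_name))
  snap <- core_state(g)
  stored_name <- g$layers$name[idx]
  lid <- g$layers$id[idx]
  victims <- names(g$nodes)[vapply(g$nodes, function(n) n$layer_id == lid,
                                   logical(1))]
  for (v in victims) g <- remove_node_impl(g, v, trans)
  g$layers <- g$layers[g$layers$id != lid, , drop = FALSE]
  old_ids <- g$layers$id
  g$layers$id <- seq_len(nrow(g$layers))
  rownames(g$layers) <- NULL
  if (length(old_ids)) {
    remap <- stats::setNames(g$layers$id, old_ids)
    g$nodes <- lapply(g$nodes, function(n) {
      n$layer_id <- unname(remap[[as.character(n$layer_id)]])
      n
    })
  }
  push_record(g, "remove_layer",
              sprintf("removed layer '%s' with %d node(s)%s", stored_name,
                      length(victims),
                      if (trans) ", preserving transitivity" else ""),
              snap)
}

# ---- nodes ------------------------------------------------------------------

#' Add a node to a layer
#'
#' Node names are the node identity and must be unique across the whole
#' graph, not merely within a layer.
#'
#' @param g An `mlgraph`.
#' @param node_name Non-empty, graph-wide unique node name.
#' @param layer_name Name of an existing layer (case-insensitive).
#' @param attributes Named list of scalar attributes (string/number/logical).
#' @return The updated graph.
#' @export
add_node <- function(g, node_name, layer_name, attributes = list()) {
  assert_mlgraph(g)
  check_string(node_name, "node name")
  check_string(layer_name, "layer name")
  attrs <- validate_attrs(attributes)
  idx <- layer_index(g, layer_name)
  if (is.na(idx)) err_not_found(sprintf("layer '%s' does not exist", layer_name))
  if (node_exists(g, node_name)) {
    err_duplicate(sprintf("node '%s' already exists in the graph", node_name))
  }
  snap <- core_state(g)
  g$nodes[[node_name]] <- list(name = node_name, layer_id = g$layers$id[idx],
                               attributes = attrs)
  push_record(g, "add_node",
              sprintf("added node '%s' to layer '%s'", node_name,
                      g$layers$name[idx]),
              snap)
}

#' Remove a node (optionally preserving reachability)
#'
#' With `trans = TRUE` the transitive shortcut edges planned by
#' [plan_transitive_edges()] are inserted before the node and its incident
#' edges are removed, so the reachability relation on the surviving nodes is
#' unchanged. The combination is one atomic, singly-undoable history step.
#'
#' @param g An `mlgraph`.
#' @param node_name Name of an existing node.
#' @param trans Logical; insert transitive shortcut edges first.
#' @return The updated graph.
#' @export
remove_node <- function(g, node_name, trans = FALSE) {
  assert_mlgraph(g)
  check_string(node_name, "node name")
  if (!node_exists(g, node_name)) {
    err_not_found(sprintf("node '%s' does not exist", node_name))
  }
  snap <- core_state(g)
  g <- remove_node_impl(g, node_name, trans)
  tag <- if (trans) "remove_node_transitive" else "remove_node"
  push_record(g, tag,
              sprintf("removed node '%s'%s", node_name,
                      if (trans) " with transitive shortcut edges" else ""),
              snap)
}

remove_node_impl <- function(g, node_name, trans) {
  if (trans) {
    plan <- plan_transitive_edges(g, node_name)
    for (ne in plan$new_edges) {
      g <- append_edge(g, ne$source, ne$target, ne$attributes)
    }
  }
  keep <- vapply(g$edges,
                 function(e) e$source != node_name && e$target != node_name,
                 logical(1))
  g$edges <- g$edges[keep]
  g$nodes[[node_name]] <- NULL
  g
}

# ---- edges ------------------------------------------------------------------

#' Add an edge between two existing nodes
#'
#' Intra-layer and inter-layer edges are both legal. Parallel edges between
#' the same pair of nodes are permitted only if their attribute maps differ;
#' an exact duplicate (same endpoints, same attributes) is rejected, as are
#' self-loops. In an undirected graph `(source, target)` and
#' `(target, source)` denote the same edge.
#'
#' @param g An `mlgraph`.
#' @param source,target Names of existing nodes.
#' @param attributes Named list of scalar attributes.
#' @return The updated graph.
#' @export
add_edge <- function(g, source, target, attributes = list()) {
  assert_mlgraph(g)
  check_string(source, "source node name")
  check_string(target, "target node name")
  attrs <- validate_attrs(attributes)
  if (!node_exists(g, source)) err_not_found(sprintf("node '%s' does not exist", source))
  if (!node_exists(g, target)) err_not_found(sprintf("node '%s' does not exist", target))
  if (source == target) err_validation("self-loops are not permitted")
  if (edge_dup_exists(g, source, target, attrs)) {
    err_duplicate(sprintf(
      "an edge %s-%s with identical attributes already exists", source, target))
  }
  snap <- core_state(g)
  g <- append_edge(g, source, target, attrs)
  push_record(g, "add_edge",
              sprintf("added edge %s %s %s", source,
                      if (g$directed) "->" else "--", target),
              snap)
}

append_edge <- function(g, source, target, attributes) {
  id <- g$next_edge_id
  g$edges[[length(g$edges) + 1L]] <- list(edge_id = id, source = source,
                                          target = target,
                                          attributes = attributes)
  g$next_edge_id <- id + 1L
  g
}

#' Remove one or all matching edges
#'
#' An edge matches when its endpoints agree (orientation-insensitive for
#' undirected graphs) and, if `attributes` is supplied, its attribute map is
#' exactly equal. With `multi = TRUE` all matches are removed; otherwise the
#' match must be unique.
#'
#' @param g An `mlgraph`.
#' @param source,target Endpoint node names.
#' @param attributes Optional named list; exact attribute filter.
#' @param multi Logical; remove every match instead of requiring uniqueness.
#' @return The updated graph.
#' @export
remove_edge <- function(g, source, target, attributes = NULL, multi = FALSE) {
  assert_mlgraph(g)
  check_string(source, "source node name")
  check_string(target, "target node name")
  filt <- if (is.null(attributes)) NULL else validate_attrs(attributes)
  hit <- vapply(g$edges, function(e) {
    same_endpoints(g, e, source, target) &&
      (is.null(filt) || attrs_equal(e$attributes, filt))
  }, logical(1))
  n_hit <- sum(hit)
  if (n_hit == 0L) {
    err_not_found(sprintf("no edge %s-%s matches", source, target))
  }
  if (n_hit > 1L && !multi) {
    err_ambiguous(sprintf(
      "%d parallel edges %s-%s match; pass attributes to disambiguate or multi = TRUE",
      n_hit, source, target))
  }
  snap <- core_state(g)
  g$edges <- g$edges[!hit]
  push_record(g, "remove_edge",
              sprintf("removed %d edge(s) %s-%s", n_hit, source, target),
              snap)
}

# ---- queries ----------------------------------------------------------------

#' List the layers of a graph
#' @param g An `mlgraph`.
#' @return A data frame with columns `id` and `name`, in layer order.
#' @export
get_layers <- function(g) {
  assert_mlgraph(g)
  g$layers
}

# Attribute-union data frame for a list of node/edge records. Columns appear
# in first-seen order; a record missing a key gets NA. A key whose values mix
# types across records falls back to character.
attr_union_columns <- function(records) {
  keys <- unique(unlist(lapply(records, function(r) names(r$attributes))))
  cols <- list()
  for (k in keys) {
    vals <- lapply(records, function(r) r$attributes[[k]])
    types <- unique(vapply(vals[!vapply(vals, is.null, logical(1))],
                           function(v) class(v)[1], character(1)))
    col <- if (length(types) == 1L && types %in% c("numeric", "logical")) {
      vapply(vals, function(v) if (is.null(v)) NA else v,
             if (types == "numeric") numeric(1) else logical(1))
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v),
             character(1))
    }
    cols[[k]] <- unname(col)
  }
  cols
}

#' List nodes, optionally restricted to one layer
#' @param g An `mlgraph`.
#' @param layer_name Optional layer name (case-insensitive) to filter by.
#' @return A data frame with columns `name`, `layer` and one column per
#'   attribute key in use (NA where a node lacks the attribute).
#' @export
get_nodes <- function(g, layer_name = NULL) {
  assert_mlgraph(g)
  recs <- g$nodes
  if (!is.null(layer_name)) {
    idx <- layer_index(g, layer_name)
    if (is.na(idx)) err_not_found(sprintf("layer '%s' does not exist", layer_name))
    lid <- g$layers$id[idx]
    recs <- recs[vapply(recs, function(n) n$layer_id == lid, logical(1))]
  }
  out <- data.frame(
    name = unname(vapply(recs, `[[`, character(1), "name")),
    layer = unname(vapply(recs, function(n) layer_name_of_id(g, n$layer_id),
                          character(1))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  ac <- attr_union_columns(recs)
  for (col in names(ac)) out[[col]] <- ac[[col]]
  out
}

#' Get the attribute map of one node
#' @param g An `mlgraph`.
#' @param node_name Name of an existing node.
#' @return A named list of scalar attributes (possibly empty).
#' @export
get_node_attributes <- function(g, node_name) {
  assert_mlgraph(g)
  check_string(node_name, "node name")
  if (!node_exists(g, node_name)) {
    err_not_found(sprintf("node '%s' does not exist", node_name))
  }
  g$nodes[[node_name]]$attributes
}

#' Get the layer a node belongs to
#' @param g An `mlgraph`.
#' @param node_name Name of an existing node.
#' @return The layer name (stored spelling).
#' @export
get_layer_of <- function(g, node_name) {
  assert_mlgraph(g)
  check_string(node_name, "node name")
  if (!node_exists(g, node_name)) {
    err_not_found(sprintf("node '%s' does not exist", node_name))
  }
  layer_name_of_id(g, g$nodes[[node_name]]$layer_id)
}

#' List edges, optionally filtered
#'
#' @param g An `mlgraph`.
#' @param between Optional filter: a character vector of length 2 is read as a
#'   pair of layer names and selects edges with one endpoint in each layer; a
#'   single string is read as a node name and selects its incident edges.
#' @return A data frame with columns `edge_id`, `source`, `target` and one
#'   column per attribute key in use.
#' @export
get_edges <- function(g, between = NULL) {
  assert_mlgraph(g)
  recs <- g$edges
  if (!is.null(between)) {
    if (!is.character(between) || !length(between) %in% c(1L, 2L)) {
      err_validation("'between' must be one node name or two layer names")
    }
    if (length(between) == 2L) {
      idx <- vapply(between, function(l) layer_index(g, l), integer(1))
      if (anyNA(idx)) {
        err_not_found(sprintf("layer '%s' does not exist", between[is.na(idx)][1]))
      }
      lids <- g$layers$id[idx]
      lid_of <- function(nm) g$nodes[[nm]]$layer_id
      recs <- recs[vapply(recs, function(e) {
        a <- lid_of(e$source); b <- lid_of(e$target)
        (a == lids[1] && b == lids[2]) || (a == lids[2] && b == lids[1])
      }, logical(1))]
    } else {
      if (!node_exists(g, between)) {
        err_not_found(sprintf("node '%s' does not exist", between))
      }
      recs <- recs[vapply(recs, function(e) {
        e$source == between || e$target == between
      }, logical(1))]
    }
  }
  out <- data.frame(
    edge_id = unname(vapply(recs, function(e) as.integer(e$edge_id), integer(1))),
    source = unname(vapply(recs, `[[`, character(1), "source")),
    target = unname(vapply(recs, `[[`, character(1), "target")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  ac <- attr_union_columns(recs)
  for (col in names(ac)) out[[col]] <- ac[[col]]
  out
}

# ---- summary / print --------------------------------------------------------

#' @export
print.mlgraph <- function(x, ...) {
  cat(sprintf("mlgraph '%s': %s, %d layer(s), %d node(s), %d edge(s)\n",
              x$name, if (x$directed) "directed" else "undirected",
              nrow(x$layers), length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Summarise a multilayer graph
#'
#' Prints (and invisibly returns) a text report: directedness, per-layer node
#' counts, edge count and history depth. A pure query; the graph is not
#' modified.
#'
#' @param object An `mlgraph`.
#' @param ... Ignored.
#' @return Invisibly, the report as a character vector.
#' @export
summary.mlgraph <- function(object, ...) {
  g <- object
  lines <- c(
    sprintf("Multilayer graph '%s' (%s)", g$name,
            if (g$directed) "directed" else "undirected"),
    sprintf("Layers: %d", nrow(g$layers))
  )
  for (i in seq_len(nrow(g$layers))) {
    lid <- g$layers$id[i]
    n <- sum(vapply(g$nodes, function(nd) nd$layer_id == lid, logical(1)))
    lines <- c(lines, sprintf("  [%d] %s: %d node(s)", lid, g$layers$name[i], n))
  }
  lines <- c(lines,
             sprintf("Nodes: %d", length(g$nodes)),
             sprintf("Edges: %d", length(g$edges)),
             sprintf("History: %d recorded modification(s)", length(g$history)))
  cat(lines, sep = "\n")
  invisible(lines)
}

# ---- integrity / equality ---------------------------------------------------

#' Check all structural invariants of a multilayer graph
#'
#' Verifies layer-id contiguity and name uniqueness, layer-disjointness
#' (every node on exactly one live layer), node-name uniqueness, referential
#' integrity of edge endpoints, absence of self-loops and of exact duplicate
#' edges. Errors (with a classed condition) on the first violation.
#'
#' @param g An `mlgraph`.
#' @return Invisibly `TRUE` when all invariants hold.
#' @export
validate_graph <- function(g) {
  assert_mlgraph(g)
  k <- nrow(g$layers)
  if (!identical(g$layers$id, seq_len(k))) {
    err_validation("layer ids are not the contiguous sequence 1..k")
  }
  if (anyDuplicated(tolower(g$layers$name))) {
    err_validation("duplicate layer names (case-insensitive)")
  }
  nms <- vapply(g$nodes, `[[`, character(1), "name")
  if (!identical(unname(nms), names(g$nodes)) || anyDuplicated(nms)) {
    err_validation("node name index is inconsistent or duplicated")
  }
  for (n in g$nodes) {
    if (!n$layer_id %in% g$layers$id) {
      err_validation(sprintf("node '%s' references missing layer id %d",
                             n$name, n$layer_id))
    }
  }
  seen_ids <- integer()
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    if (!node_exists(g, e$source) || !node_exists(g, e$target)) {
      err_validation(sprintf("edge %d has a dangling endpoint", e$edge_id))
    }
    if (e$source == e$target) err_validation("self-loop present")
    if (e$edge_id %in% seen_ids) err_validation("duplicate edge id")
    seen_ids <- c(seen_ids, e$edge_id)
    for (j in seq_len(i - 1L)) {
      o <- g$edges[[j]]
      if (same_endpoints(g, o, e$source, e$target) &&
          attrs_equal(o$attributes, e$attributes)) {
        err_validation(sprintf("exact duplicate edges %s-%s", e$source, e$target))
      }
    }
  }
  invisible(TRUE)
}

normalise_record <- function(r) {
  if (length(r$attributes) == 0L) {
    r$attributes <- structure(list(), names = character())
  } else {
    r$attributes <- r$attributes[order(names(r$attributes))]
  }
  r
}

#' Deep equality of two multilayer graphs
#'
#' Compares name, directedness, layers, nodes and edges (insertion order and
#' attribute maps included; attribute key order is normalised). The
#' modification history is ignored, since two routes to the same state are
#' the same graph.
#'
#' @param g1,g2 `mlgraph` objects.
#' @param include_ids Logical; also require identical edge ids (default). Set
#'   `FALSE` to compare graphs whose edge ids diverged through deletions.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(g1, g2, include_ids = TRUE) {
  assert_mlgraph(g1); assert_mlgraph(g2)
  if (!identical(g1$name, g2$name)) return(FALSE)
  if (!identical(g1$directed, g2$directed)) return(FALSE)
  l1 <- g1$layers; l2 <- g2$layers
  rownames(l1) <- rownames(l2) <- NULL
  if (!identical(l1, l2)) return(FALSE)
  strip_edge <- function(e) {
    e <- normalise_record(e)
    if (!include_ids) e$edge_id <- NULL
    e
  }
  identical(lapply(g1$nodes, normalise_record),
            lapply(g2$nodes, normalise_record)) &&
    identical(lapply(g1$edges, strip_edge), lapply(g2$edges, strip_edge))
}
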