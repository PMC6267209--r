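# Layer-based merge of two multilayer graphs. Layers are matched across
# graphs by (case-insensitive) name — ids are graph-local. Shared content is
# deduplicated: a node present in both graphs (same name, same layer) appears
# once, with the union of its attributes (the first graph wins conflicts);
# an edge of the second graph is skipped when an edge with identical
# endpoints and attributes already exists.

#' Merge two multilayer graphs layer by layer
#'
#' The result contains the first graph's layers followed by the second's
#' layers not already present by name, with ids recompacted to `1..k`; the
#' union of the node sets (a node sharing its name across both graphs must sit
#' on the same layer in both and is merged, first graph winning attribute
#' conflicts); and the union of the edges with exact duplicates (same
#' endpoints and attributes) deduplicated.
#'
#' The merged graph starts a fresh modification history: the merge is its
#' first, non-invertible record — a merge is a new view origin and cannot be
#' undone into its parents.
#'
#' @param g1,g2 `mlgraph` objects with equal directedness.
#' @return The merged `mlgraph`. Its name is `g1`'s name when both inputs
#'   share it, otherwise `"<name1>+<name2>"`.
#' @examples
#' a <- add_layer(mlgraph("a"), "gene")
#' a <- add_node(a, "TP53", "gene")
#' b <- add_layer(mlgraph("b"), "gene")
#' b <- add_node(b, "TP53", "gene")
#' m <- merge_graphs(a, b)   # one layer, one node
#' @export
merge_graphs <- function(g1, g2) {
  assert_mlgraph(g1)
  assert_mlgraph(g2)
  if (!identical(g1$directed, g2$directed)) {
    err_incompatible("cannot merge a directed with an undirected graph")
  }

  res <- g1
  res$history <- list()

  for (ln in g2$layers$name) {
    if (is.na(layer_index(res, ln))) res <- add_layer_impl(res, ln)
  }

  for (nr in g2$nodes) {
    g2_layer <- layer_name_of_id(g2, nr$layer_id)
    existing <- res$nodes[[nr$name]]
    if (!is.null(existing)) {
      res_layer <- layer_name_of_id(res, existing$layer_id)
      if (tolower(res_layer) != tolower(g2_layer)) {
        err_layer_conflict(sprintf(
          "node '%s' sits on layer '%s' in the first graph but '%s' in the second",
          nr$name, res_layer, g2_layer))
      }
      extra <- nr$attributes[setdiff(names(nr$attributes),
                                     names(existing$attributes))]
      if (length(extra)) existing$attributes <- c(existing$attributes, extra)
      res$nodes[[nr$name]] <- existing
    } else {
      lid <- res$layers$id[layer_index(res, g2_layer)]
      res$nodes[[nr$name]] <- list(name = nr$name, layer_id = lid,
                                   attributes = nr$attributes)
    }
  }

  for (e in g2$edges) {
    if (!edge_dup_exists(res, e$source, e$target, e$attributes)) {
      res <- append_edge(res, e$source, e$target, e$attributes)
    }
  }

  if (!identical(g1$name, g2$name)) {
    res$name <- paste0(g1$name, "+", g2$name)
  }
  push_record(res, "merge",
              sprintf("merged graphs '%s' and '%s'", g1$name, g2$name),
              snapshot = NULL, invertible = FALSE)
}

#' @rdname merge_graphs
#' @param x,y `mlgraph` objects (S3 method interface for [merge()]).
#' @param ... Ignored.
#' @export
merge.mlgraph <- function(x, y, ...) merge_graphs(x, y)
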