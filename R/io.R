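# Three-file CSV serialization and CX (Cytoscape Cyberinfrastructure Network
# Interchange Format) export.
#
# CSV dialect: RFC 4180 quoting, UTF-8, header row always present.
#   <base>_layers.csv  id,name
#   <base>_nodes.csv   name,layer,<union of attribute keys>
#   <base>_edges.csv   source,target,<union of attribute keys>
# Rows follow insertion order; a missing attribute is an empty cell. CSV is
# untyped, so import re-types cells: "TRUE"/"FALSE" -> logical, numeric-
# parsable -> double, anything else -> string. Directedness has no slot in
# the schema and is a required import parameter; the modification history is
# runtime-only and never serialized.

csv_cell <- function(v) {
  if (is.null(v)) return(NA_character_)
  if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
  as.character(v)
}

parse_cell <- function(s) {
  if (s == "TRUE") return(TRUE)
  if (s == "FALSE") return(FALSE)
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

csv_paths <- function(base_path) {
  c(layers = paste0(base_path, "_layers.csv"),
    nodes = paste0(base_path, "_nodes.csv"),
    edges = paste0(base_path, "_edges.csv"))
}

write_csv_file <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) err_io(sprintf("cannot write CSV file '%s'", path))
  path
}

attr_cell_columns <- function(records) {
  keys <- unique(unlist(lapply(records, function(r) names(r$attributes))))
  cols <- list()
  for (k in keys) {
    cols[[k]] <- vapply(records, function(r) csv_cell(r$attributes[[k]]),
                        character(1), USE.NAMES = FALSE)
  }
  cols
}

#' Export a graph to the three-file CSV schema
#'
#' Writes `<base>_layers.csv` (columns `id,name`), `<base>_nodes.csv`
#' (columns `name,layer,` then the union of node attribute keys) and
#' `<base>_edges.csv` (columns `source,target,` then the union of edge
#' attribute keys). Missing attributes are empty cells; rows follow insertion
#' order; output is deterministic (identical graph, byte-identical files).
#' Directedness and history are not serialized (see [import_csv()]).
#'
#' @param g An `mlgraph`.
#' @param base_path Path prefix for the three files; its directory must exist.
#' @return Invisibly, a named character vector of the three paths
#'   (`layers`, `nodes`, `edges`).
#' @export
export_csv <- function(g, base_path) {
  assert_mlgraph(g)
  check_string(base_path, "base path")
  if (!dir.exists(dirname(base_path))) {
    err_io(sprintf("directory '%s' does not exist", dirname(base_path)))
  }
  paths <- csv_paths(base_path)

  write_csv_file(g$layers, paths[["layers"]])

  nodes_df <- data.frame(
    name = unname(vapply(g$nodes, `[[`, character(1), "name")),
    layer = unname(vapply(g$nodes, function(n) layer_name_of_id(g, n$layer_id),
                          character(1))),
    stringsAsFactors = FALSE
  )
  if (length(g$nodes) == 0L) nodes_df <- data.frame(name = character(),
                                                    layer = character(),
                                                    stringsAsFactors = FALSE)
  for (col in names(nc <- attr_cell_columns(g$nodes))) nodes_df[[col]] <- nc[[col]]
  write_csv_file(nodes_df, paths[["nodes"]])

  edges_df <- data.frame(
    source = unname(vapply(g$edges, `[[`, character(1), "source")),
    target = unname(vapply(g$edges, `[[`, character(1), "target")),
    stringsAsFactors = FALSE
  )
  if (length(g$edges) == 0L) edges_df <- data.frame(source = character(),
                                                    target = character(),
                                                    stringsAsFactors = FALSE)
  for (col in names(ec <- attr_cell_columns(g$edges))) edges_df[[col]] <- ec[[col]]
  write_csv_file(edges_df, paths[["edges"]])

  invisible(paths)
}

read_csv_file <- function(path, required) {
  if (!file.exists(path)) err_io(sprintf("file '%s' does not exist", path))
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = character(), fileEncoding = "UTF-8"),
    error = function(e) err_schema(sprintf("cannot parse '%s' as CSV: %s",
                                           path, conditionMessage(e))))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    err_schema(sprintf("'%s' lacks required column(s): %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  df
}

row_attrs <- function(df, i, skip) {
  keys <- setdiff(names(df), skip)
  out <- list()
  for (k in keys) {
    cell <- df[[k]][i]
    if (nzchar(cell)) out[[k]] <- parse_cell(cell)
  }
  out
}

#' Import a graph from the three-file CSV schema
#'
#' Reconstructs a graph written by [export_csv()]:
#' `import_csv(export_csv(g))` is deep-equal to `g` up to history (the
#' imported graph starts with an empty history). Empty attribute cells mean
#' the attribute is absent. Referential problems — a node citing an unknown
#' layer, an edge citing an unknown node, duplicate node names, exact
#' duplicate edges — raise a schema error.
#'
#' @param nodes_path,edges_path,layers_path Paths to the three CSV files.
#' @param name Graph name for the reconstructed graph.
#' @param directed Logical; the schema does not record directedness, so the
#'   caller must state it.
#' @return The reconstructed `mlgraph` with empty history.
#' @export
import_csv <- function(nodes_path, edges_path, layers_path, name,
                       directed = FALSE) {
  layers <- read_csv_file(layers_path, c("id", "name"))
  nodes <- read_csv_file(nodes_path, c("name", "layer"))
  edges <- read_csv_file(edges_path, c("source", "target"))

  ids <- suppressWarnings(as.integer(layers$id))
  if (anyNA(ids) || !identical(sort(ids), seq_len(nrow(layers)))) {
    err_schema("layer ids must be exactly 1..k")
  }
  layers <- layers[order(ids), , drop = FALSE]

  g <- mlgraph(name, directed)
  for (ln in layers$name) {
    if (!is.na(layer_index(g, ln))) err_schema("duplicate layer names")
    g <- add_layer_impl(g, ln)
  }

  if (anyDuplicated(nodes$name)) {
    err_schema(sprintf("duplicate node name '%s' in '%s'",
                       nodes$name[duplicated(nodes$name)][1], nodes_path))
  }
  for (i in seq_len(nrow(nodes))) {
    idx <- layer_index(g, nodes$layer[i])
    if (is.na(idx)) {
      err_schema(sprintf("node '%s' references unknown layer '%s'",
                         nodes$name[i], nodes$layer[i]))
    }
    g$nodes[[nodes$name[i]]] <- list(
      name = nodes$name[i], layer_id = g$layers$id[idx],
      attributes = validate_attrs(row_attrs(nodes, i, c("name", "layer"))))
  }

  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$target[i]
    if (!node_exists(g, s) || !node_exists(g, t)) {
      err_schema(sprintf("edge %s-%s references an unknown node", s, t))
    }
    if (s == t) err_schema("self-loop in edges file")
    attrs <- validate_attrs(row_attrs(edges, i, c("source", "target")))
    if (edge_dup_exists(g, s, t, attrs)) {
      err_schema(sprintf("exact duplicate edge %s-%s in edges file", s, t))
    }
    g <- append_edge(g, s, t, attrs)
  }

  g$history <- list()
  g
}

# ---- CX export ---------------------------------------------------------------

cx_attr_row <- function(po, key, value) {
  row <- list(po = po, n = key, v = value)
  if (is.logical(value)) row$d <- "boolean"
  else if (is.numeric(value)) row$d <- "double"
  row
}

#' Export a graph as a CX interchange document
#'
#' Writes a single JSON array of aspect objects following the CX convention
#' used by Cytoscape and NDEx: `metaData` (aspect names and element counts),
#' `networkAttributes` (graph name and directedness), `nodes`
#' (`@id`, `n`), `edges` (`@id`, `s`, `t`), `nodeAttributes` (one `layer`
#' entry per node plus user attributes), `edgeAttributes`, an optional
#' `cartesianLayout` taken from a layout object, and `status`. Numeric
#' node/edge ids are assigned in insertion order starting at 0.
#'
#' @param g An `mlgraph`.
#' @param path Output file path.
#' @param layout Optional `mlgraph_layout`; when given, a `cartesianLayout`
#'   aspect with its coordinates is included.
#' @return Invisibly, `path`.
#' @seealso [validate_cx()]
#' @export
export_cx <- function(g, path, layout = NULL) {
  assert_mlgraph(g)
  check_string(path, "path")
  if (!is.null(layout) && !inherits(layout, "mlgraph_layout")) {
    err_validation("'layout' must be an mlgraph_layout")
  }

  node_names <- names(g$nodes)
  node_id <- stats::setNames(seq_along(node_names) - 1L, node_names)

  nodes_aspect <- unname(lapply(seq_along(node_names), function(i) {
    list(`@id` = i - 1L, n = node_names[i])
  }))

  edges_aspect <- unname(lapply(seq_along(g$edges), function(i) {
    e <- g$edges[[i]]
    list(`@id` = i - 1L, s = unname(node_id[[e$source]]),
         t = unname(node_id[[e$target]]))
  }))

  node_attrs <- list()
  for (nm in node_names) {
    rec <- g$nodes[[nm]]
    node_attrs[[length(node_attrs) + 1L]] <-
      cx_attr_row(unname(node_id[[nm]]), "layer", layer_name_of_id(g, rec$layer_id))
    for (k in names(rec$attributes)) {
      node_attrs[[length(node_attrs) + 1L]] <-
        cx_attr_row(unname(node_id[[nm]]), k, rec$attributes[[k]])
    }
  }

  edge_attrs <- list()
  for (i in seq_along(g$edges)) {
    for (k in names(g$edges[[i]]$attributes)) {
      edge_attrs[[length(edge_attrs) + 1L]] <-
        cx_attr_row(i - 1L, k, g$edges[[i]]$attributes[[k]])
    }
  }

  network_attrs <- list(
    list(n = "name", v = g$name),
    list(n = "directed", v = g$directed, d = "boolean")
  )

  cartesian <- NULL
  if (!is.null(layout)) {
    co <- layout$coords
    unknown <- setdiff(co$name, node_names)
    if (length(unknown)) {
      err_validation(sprintf("layout covers unknown node '%s'", unknown[1]))
    }
    cartesian <- unname(lapply(seq_len(nrow(co)), function(r) {
      row <- list(node = unname(node_id[[co$name[r]]]),
                  x = co$x[r], y = co$y[r])
      if ("z" %in% names(co)) row$z <- co$z[r]
      row
    }))
  }

  meta <- list(
    list(name = "networkAttributes", elementCount = length(network_attrs)),
    list(name = "nodes", elementCount = length(nodes_aspect)),
    list(name = "edges", elementCount = length(edges_aspect)),
    list(name = "nodeAttributes", elementCount = length(node_attrs)),
    list(name = "edgeAttributes", elementCount = length(edge_attrs))
  )
  if (!is.null(cartesian)) {
    meta[[length(meta) + 1L]] <- list(name = "cartesianLayout",
                                      elementCount = length(cartesian))
  }

  doc <- list(
    list(metaData = meta),
    list(networkAttributes = network_attrs),
    list(nodes = nodes_aspect),
    list(edges = edges_aspect),
    list(nodeAttributes = node_attrs),
    list(edgeAttributes = edge_attrs)
  )
  if (!is.null(cartesian)) doc[[length(doc) + 1L]] <- list(cartesianLayout = cartesian)
  doc[[length(doc) + 1L]] <- list(status = list(list(error = "", success = TRUE)))

  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(as.character(json), path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) err_io(sprintf("cannot write CX document to '%s'", path))
  invisible(path)
}

#' Validate the internal consistency of a CX document
#'
#' Checks that the file is a single JSON array of aspect objects; that
#' `metaData` element counts equal the actual aspect lengths; that every edge
#' references declared node ids; that every node carries exactly one
#' `nodeAttributes` entry named `layer`; and that the `status` aspect reports
#' success. Raises a schema error on the first violation.
#'
#' @param path Path to a CX JSON file.
#' @return Invisibly `TRUE` when the document is consistent.
#' @export
validate_cx <- function(path) {
  if (!file.exists(path)) err_io(sprintf("file '%s' does not exist", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) err_schema(sprintf(
                    "cannot parse '%s' as JSON: %s", path, conditionMessage(e))))
  if (!is.list(doc)) err_schema("CX document must be a JSON array")
  aspects <- list()
  for (el in doc) {
    if (!is.list(el) || length(el) != 1L || is.null(names(el))) {
      err_schema("each CX element must be a single-aspect object")
    }
    aspects[[names(el)]] <- el[[1L]]
  }
  for (nm in c("metaData", "nodes", "edges", "nodeAttributes", "status")) {
    if (is.null(aspects[[nm]])) err_schema(sprintf("missing aspect '%s'", nm))
  }
  for (m in aspects$metaData) {
    declared <- m$elementCount
    actual <- length(aspects[[m$name]])
    if (is.null(aspects[[m$name]]) || !identical(as.integer(declared),
                                                 as.integer(actual))) {
      err_schema(sprintf("metaData count for '%s' (%s) != aspect length (%d)",
                         m$name, declared, actual))
    }
  }
  node_ids <- vapply(aspects$nodes, function(n) as.integer(n[["@id"]]),
                     integer(1))
  if (anyDuplicated(node_ids)) err_schema("duplicate node ids")
  for (e in aspects$edges) {
    if (!as.integer(e$s) %in% node_ids || !as.integer(e$t) %in% node_ids) {
      err_schema(sprintf("edge %s references an undeclared node id", e[["@id"]]))
    }
  }
  layer_of <- integer()
  for (a in aspects$nodeAttributes) {
    if (identical(a$n, "layer")) layer_of <- c(layer_of, as.integer(a$po))
  }
  if (!identical(sort(layer_of), sort(node_ids))) {
    err_schema("every node must carry exactly one 'layer' nodeAttributes entry")
  }
  st <- aspects$status[[1L]]
  if (!isTRUE(st$success)) err_schema("status aspect does not report success")
  invisible(TRUE)
}

# ---- fixtures ----------------------------------------------------------------

#' The built-in demo graph
#'
#' A fixed, three-layer undirected graph (layers `disease`, `drug`, `gene`)
#' used throughout the documentation and tests: each layer holds at least two
#' nodes, there is at least one intra-layer and one inter-layer edge, and at
#' least one edge carries attributes. Deterministic: two calls return
#' deep-equal graphs.
#'
#' @return An `mlgraph`.
#' @examples
#' summary(demo_graph())
#' @export
demo_graph <- function() {
  g <- mlgraph("demo", directed = FALSE)
  g <- add_layer(g, "disease")
  g <- add_layer(g, "drug")
  g <- add_layer(g, "gene")
  g <- add_node(g, "influenza", "disease", list(icd10 = "J11"))
  g <- add_node(g, "asthma", "disease", list(icd10 = "J45", chronic = TRUE))
  g <- add_node(g, "oseltamivir", "drug")
  g <- add_node(g, "salbutamol", "drug")
  g <- add_node(g, "theophylline", "drug")
  g <- add_node(g, "IFNG", "gene", list(chromosome = 12))
  g <- add_node(g, "IL4", "gene", list(chromosome = 5))
  g <- add_node(g, "ADRB2", "gene", list(chromosome = 5))
  g <- add_edge(g, "oseltamivir", "influenza", list(relation = "treats"))
  g <- add_edge(g, "salbutamol", "asthma", list(relation = "treats"))
  g <- add_edge(g, "theophylline", "asthma", list(relation = "treats"))
  g <- add_edge(g, "salbutamol", "ADRB2", list(relation = "agonist"))
  g <- add_edge(g, "IL4", "asthma")
  g <- add_edge(g, "IFNG", "influenza")
  g <- add_edge(g, "IL4", "IFNG", list(relation = "antagonism"))  # intra-layer
  g <- add_edge(g, "salbutamol", "theophylline")                  # intra-layer
  g
}

#' Seeded random multilayer graph generator
#'
#' Builds `n_layers` layers named `L1..Lk`, each holding `nodes_per_layer`
#' nodes named `L<i>_N<j>`, then adds an edge independently with probability
#' `edge_prob` for every unordered node pair (every ordered pair of distinct
#' nodes when directed). Reproducible: the same seed gives a deep-equal
#' graph; the session RNG is not disturbed.
#'
#' @param n_layers Number of layers (>= 1).
#' @param nodes_per_layer Nodes per layer (>= 1).
#' @param edge_prob Edge probability in \[0, 1\].
#' @param directed Logical.
#' @param seed Integer RNG seed.
#' @return An `mlgraph`.
#' @export
random_multilayer <- function(n_layers, nodes_per_layer, edge_prob,
                              directed = FALSE, seed = 1L) {
  if (!is.numeric(n_layers) || length(n_layers) != 1L || n_layers < 1) {
    err_validation("'n_layers' must be >= 1")
  }
  if (!is.numeric(nodes_per_layer) || length(nodes_per_layer) != 1L ||
      nodes_per_layer < 1) {
    err_validation("'nodes_per_layer' must be >= 1")
  }
  if (!is.numeric(edge_prob) || length(edge_prob) != 1L || is.na(edge_prob) ||
      edge_prob < 0 || edge_prob > 1) {
    err_validation("'edge_prob' must be in [0, 1]")
  }
  n_layers <- as.integer(n_layers)
  nodes_per_layer <- as.integer(nodes_per_layer)

  g <- mlgraph(sprintf("random_%d", as.integer(seed)), directed = directed)
  for (i in seq_len(n_layers)) g <- add_layer_impl(g, sprintf("L%d", i))
  for (i in seq_len(n_layers)) {
    for (j in seq_len(nodes_per_layer)) {
      nm <- sprintf("L%d_N%d", i, j)
      g$nodes[[nm]] <- list(name = nm, layer_id = i,
                            attributes = structure(list(), names = character()))
    }
  }
  all_names <- names(g$nodes)
  n <- length(all_names)
  g <- with_seed(as.integer(seed), {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        if (!directed && a > b) next
        if (stats::runif(1) < edge_prob) {
          g <- append_edge(g, all_names[a], all_names[b],
                           structure(list(), names = character()))
        }
      }
    }
    g
  })
  g
}
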