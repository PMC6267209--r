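# Every mutating operation appends one ChangeRecord. A record stores a full
# snapshot of the pre-operation core state (layers, nodes, edges, edge-id
# counter), so compound operations (transitive node removal, layer removal)
# invert atomically without re-deriving plans. Queries are never recorded.

push_record <- function(g, op_tag, description, snapshot, invertible = TRUE) {
  n <- length(g$history)
  seq_no <- if (n) g$history[[n]]$sequence_no + 1L else 1L
  g$history[[n + 1L]] <- list(
    sequence_no = seq_no,
    op_tag = op_tag,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    description = description,
    snapshot = snapshot,
    invertible = invertible
  )
  g
}

#' Undo the last modifications of a graph
#'
#' Reverts the last `steps` recorded modifications, restoring the graph to the
#' exact earlier state (deep equality). Compound operations — transitive node
#' removal and layer removal — were recorded as single records and invert
#' atomically as one step. A merged graph starts a fresh history whose first
#' record (the merge itself) is not invertible: undo cannot cross back into
#' the parent graphs.
#'
#' @param g An `mlgraph`.
#' @param steps Positive number of modifications to revert (default 1).
#' @return The reverted graph.
#' @export
undo <- function(g, steps = 1L) {
  assert_mlgraph(g)
  if (!is.numeric(steps) || length(steps) != 1L || is.na(steps) ||
      steps < 1L || steps != as.integer(steps)) {
    err_validation("'steps' must be a positive integer")
  }
  steps <- as.integer(steps)
  n <- length(g$history)
  if (steps > n) {
    err_underflow(sprintf("cannot undo %d step(s): history holds %d", steps, n))
  }
  popped <- g$history[(n - steps + 1L):n]
  if (!all(vapply(popped, `[[`, logical(1), "invertible"))) {
    err_underflow("cannot undo across a merge origin")
  }
  g <- restore_core(g, popped[[1L]]$snapshot)
  g$history <- g$history[seq_len(n - steps)]
  g
}

#' The modification history of a graph
#'
#' Chronological log of all mutations still in effect (undone steps are
#' popped). This is the documentation trail of a network view: the sequence
#' of steps that produced the current state from the original graph.
#'
#' @param g An `mlgraph`.
#' @return A data frame with columns `sequence_no`, `op_tag`, `timestamp`
#'   (ISO-8601, UTC) and `description`; zero rows for a fresh graph.
#' @export
get_history <- function(g) {
  assert_mlgraph(g)
  data.frame(
    sequence_no = vapply(g$history, function(r) r$sequence_no, integer(1)),
    op_tag = vapply(g$history, `[[`, character(1), "op_tag"),
    timestamp = vapply(g$history, `[[`, character(1), "timestamp"),
    description = vapply(g$history, `[[`, character(1), "description"),
    stringsAsFactors = FALSE
  )
}

#' Export the history log as plain text
#'
#' One tab-separated line per record: sequence number, timestamp, operation
#' tag, description. History is runtime-only state — the three-file CSV
#' serialization does not carry it — so this log is the portable record of a
#' view's provenance.
#'
#' @param g An `mlgraph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_history <- function(g, path) {
  assert_mlgraph(g)
  h <- get_history(g)
  lines <- sprintf("%d\t%s\t%s\t%s", h$sequence_no, h$timestamp, h$op_tag,
                   h$description)
  ok <- tryCatch({ writeLines(lines, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) err_io(sprintf("cannot write history log to '%s'", path))
  invisible(path)
}
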