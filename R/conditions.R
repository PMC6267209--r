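# Classed conditions so callers (and the CLI) can react to failure modes
# without string-matching messages. All inherit from "mlgraph_error".

mlg_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mlgraph_error")))
}

err_validation     <- function(msg) mlg_abort(msg, "mlgraph_validation_error")
err_not_found      <- function(msg) mlg_abort(msg, "mlgraph_not_found_error")
err_duplicate      <- function(msg) mlg_abort(msg, "mlgraph_duplicate_error")
err_ambiguous      <- function(msg) mlg_abort(msg, "mlgraph_ambiguous_error")
err_underflow      <- function(msg) mlg_abort(msg, "mlgraph_underflow_error")
err_incompatible   <- function(msg) mlg_abort(msg, "mlgraph_incompatible_error")
err_layer_conflict <- function(msg) mlg_abort(msg, "mlgraph_layer_conflict_error")
err_capacity       <- function(msg) mlg_abort(msg, "mlgraph_capacity_error")
err_io             <- function(msg) mlg_abort(msg, "mlgraph_io_error")
err_schema         <- function(msg) mlg_abort(msg, "mlgraph_schema_error")
err_usage          <- function(msg) mlg_abort(msg, "mlgraph_usage_error")
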