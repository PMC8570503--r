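# Classed error conditions. Every domain error carries a subclass so callers
# (and tests) can distinguish validation failures from numeric degeneracies.

aw_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aw_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_validation  <- function(msg, ...) aw_stop("aw_validation_error", msg, ...)
abort_degenerate  <- function(msg, ...) aw_stop("aw_degenerate_geometry", msg, ...)
abort_empty       <- function(msg, ...) aw_stop("aw_empty_input", msg, ...)
abort_boundary    <- function(msg, ...) aw_stop("aw_boundary_error", msg, ...)
abort_seed        <- function(msg, ...) aw_stop("aw_seed_error", msg, ...)
abort_data        <- function(msg, ...) aw_stop("aw_data_error", msg, ...)
abort_ordering    <- function(msg, ...) aw_stop("aw_ordering_error", msg, ...)
abort_format      <- function(msg, ...) aw_stop("aw_format_error", msg, ...)
abort_sample_size <- function(msg, ...) aw_stop("aw_sample_size_error", msg, ...)
abort_undefined_statistic <- function(msg, ...) aw_stop("aw_undefined_statistic", msg, ...)
abort_undefined_parameter <- function(msg, ...) aw_stop("aw_undefined_parameter", msg, ...)
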