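# Typed error conditions so callers (notably the simulation engine) can
# distinguish recoverable numerical degeneracies from genuine misuse.

gsr_stop <- function(class, message, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "gsr_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

stop_invalid_input <- function(message, ...) {
  gsr_stop("gsr_invalid_input", message, ...)
}

# variance estimate is exactly zero (e.g. completely separated or constant
# samples), so no information / standardized statistic exists at this stage
stop_degenerate_variance <- function(message, ...) {
  gsr_stop("gsr_degenerate_variance", message, ...)
}

# p-hat on the boundary of [0,1]: the logit and its delta-method information
# are undefined
stop_boundary_effect <- function(message, ...) {
  gsr_stop("gsr_boundary_effect", message, ...)
}

# estimated information not strictly increasing across stages
stop_monotonicity <- function(message, ...) {
  gsr_stop("gsr_monotonicity", message, ...)
}

stop_numeric <- function(message, ...) {
  gsr_stop("gsr_numeric", message, ...)
}

stop_search_bound <- function(message, ...) {
  gsr_stop("gsr_search_bound", message, ...)
}

stop_parse <- function(message, ...) {
  gsr_stop("gsr_parse", message, ...)
}
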