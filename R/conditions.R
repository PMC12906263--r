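# Classed conditions so callers (and the CLI) can distinguish configuration
# problems from data problems.

sw_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "strideworks_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

config_error <- function(field, fmt, ...) {
  sw_stop("strideworks_config_error",
          "invalid configuration field '%s': %s", field, sprintf(fmt, ...))
}

param_error <- function(fmt, ...) {
  sw_stop("strideworks_param_error", fmt, ...)
}

insufficient_data_error <- function(fmt, ...) {
  sw_stop("strideworks_insufficient_data_error", fmt, ...)
}

design_error <- function(fmt, ...) {
  sw_stop("strideworks_design_error", fmt, ...)
}

schema_error <- function(fmt, ...) {
  sw_stop("strideworks_schema_error", fmt, ...)
}

data_error <- function(fmt, ...) {
  sw_stop("strideworks_data_error", fmt, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
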