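# Classed error conditions so callers (and the CLI) can map failures to
# exit codes: parameter errors (bad arguments/config), data errors (valid
# call, unusable data), format errors (malformed file).

stop_param <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("penbeat_parameter_error", "penbeat_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("penbeat_data_error", "penbeat_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("penbeat_format_error", "penbeat_error", "error")))
}
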