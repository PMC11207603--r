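# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without parsing messages.

abort_dvj <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dvj_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_format     <- function(msg, ...) abort_dvj("dvj_format_error", msg, ...)
abort_validation <- function(msg, ...) abort_dvj("dvj_validation_error", msg, ...)
abort_parameter  <- function(msg, ...) abort_dvj("dvj_parameter_error", msg, ...)
abort_detection  <- function(msg, ...) abort_dvj("dvj_detection_error", msg, ...)
abort_degenerate <- function(msg, ...) abort_dvj("dvj_degenerate_error", msg, ...)
abort_io         <- function(msg, ...) abort_dvj("dvj_io_error", msg, ...)
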