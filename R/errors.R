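# Classed conditions so callers (and the CLI) can distinguish anticipated
# data errors from programming errors.  Every anticipated failure raised by
# the readers carries class "msio_error" plus a specific subclass.

msio_stop <- function(subclass, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("msio_", subclass, "_error"), "msio_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

msio_usage_stop <- function(message) {
  stop(structure(
    class = c("msio_usage_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}
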