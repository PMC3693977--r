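# Structured conditions so callers (and the CLI exit-code mapping) can
# distinguish bad input from a bad filesystem.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("ultranet_validation_error", "ultranet_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("ultranet_format_error", "ultranet_validation_error",
              "ultranet_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("ultranet_io_error", "ultranet_error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("ultranet_lookup_error", "ultranet_validation_error",
              "ultranet_error")))
}

stop_capability <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("ultranet_capability_error", "ultranet_error")))
}
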