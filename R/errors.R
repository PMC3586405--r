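# Classed conditions used across the package. Every error inherits from
# "phl_error" so callers can catch the package's failures as a family.

phl_stop <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "phl_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

stop_invalid_input <- function(message, ...) {
  phl_stop(message, "phl_invalid_input", ...)
}

stop_no_voicing <- function(message, ...) {
  phl_stop(message, "phl_no_voicing", ...)
}

# Unvoiced material also cannot yield cycles, so the no-voicing case carries
# both classes: callers may catch either.
stop_insufficient_cycles <- function(message, unvoiced = FALSE, ...) {
  cls <- if (unvoiced) c("phl_insufficient_cycles", "phl_no_voicing")
         else "phl_insufficient_cycles"
  phl_stop(message, cls, ...)
}

stop_insufficient_frames <- function(message, ...) {
  phl_stop(message, "phl_insufficient_frames", ...)
}

stop_validation <- function(message, ...) {
  phl_stop(message, "phl_validation", ...)
}

stop_geometry <- function(message, ...) {
  phl_stop(message, "phl_geometry", ...)
}

stop_spec <- function(message, ...) {
  phl_stop(message, "phl_spec", ...)
}

stop_parse <- function(message, ...) {
  phl_stop(message, "phl_parse", ...)
}

stop_nothing_to_report <- function(message, ...) {
  phl_stop(message, "phl_nothing_to_report", ...)
}
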