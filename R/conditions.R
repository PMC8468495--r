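# classed conditions so callers can distinguish degenerate inputs from bugs
synfair_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "synfair_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}
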