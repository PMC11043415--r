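# Classed error conditions so callers (and tests) can distinguish the
# validation failure modes of the input contract.

stop_metstab <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "metstab_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
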