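# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries class c("coex_<kind>", "coex_error").

stop_coex <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("coex_", kind), "coex_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# kinds in use:
#   format_error        malformed input file (duplicates, unparseable cells)
#   domain_error        values outside the operation's domain
#   io_error            unreadable/unwritable path
#   key_not_found       requested feature/sample id absent
#   constant_feature    zero-variance seed or target
#   insufficient_samples fewer complete pairs than the regression needs
#   config_error        inconsistent tier/pipeline/simulation configuration
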