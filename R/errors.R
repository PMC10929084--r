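# Classed conditions so callers can branch on failure mode rather than
# matching message text. All inherit from "rpifuse_error".

rpi_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rpifuse_error"), call = call))
}

rpi_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rpifuse_warning")))
}
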