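# Structured conditions so callers can distinguish failure modes
# (low signal vs bad parameters vs format problems) programmatically.

of_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "omiflim_error")))
}

of_check <- function(ok, msg, class = "omiflim_invalid_parameter") {
  if (!isTRUE(ok)) of_stop(msg, class)
  invisible(TRUE)
}
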