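# Classed conditions so callers can distinguish failure modes programmatically.
# All inherit from "tm_error".

tm_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "tm_error")))
}

tm_check <- function(ok, msg, class = "tm_invalid_input") {
  if (!isTRUE(ok)) tm_stop(msg, class)
  invisible(TRUE)
}

# scalar-in-range helper used by constructors
chk_prob <- function(x, name, open = TRUE) {
  tm_check(is.numeric(x) && length(x) == 1L && is.finite(x),
           sprintf("`%s` must be a finite numeric scalar", name))
  if (open) {
    tm_check(x > 0 && x < 1, sprintf("`%s` must lie strictly in (0, 1)", name))
  } else {
    tm_check(x >= 0 && x <= 1, sprintf("`%s` must lie in [0, 1]", name))
  }
  x
}
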