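# Classed conditions so callers (and tests) can catch specific failure modes.

stop_ecgstress <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ecgstress_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @importFrom utils head
assert_that <- function(ok, class, message) {
  if (!isTRUE(ok)) stop_ecgstress(class, message)
  invisible(TRUE)
}
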