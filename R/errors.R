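## Typed conditions used across the pipeline so callers can trap a specific
## failure (e.g. a box lost during augmentation) without string matching.

.stopWith <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "echocalcError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) .stopWith(class, msg, ...)
  invisible(TRUE)
}
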