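# Classed error helper so callers can branch on failure type.
abort_pm <- function(message, class) {
  stop(structure(
    list(message = message, call = NULL),
    class = c(paste0("pairmnar_", class), "pairmnar_error", "error", "condition")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
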