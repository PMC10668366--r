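# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without parsing messages.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("bfdesign_invalid_input", "bfdesign_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("bfdesign_degenerate_data",
                                "bfdesign_invalid_input", "bfdesign_error")))
}

stop_numerical <- function(..., diagnostics = NULL) {
  stop(errorCondition(paste0(...),
                      diagnostics = diagnostics,
                      class = c("bfdesign_numerical_failure",
                                "bfdesign_error")))
}
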