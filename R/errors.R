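# Classed conditions backing the stable exit-status contract:
# input/validation problems -> "webfoot_input_error" (exit 2),
# numerical failures -> "webfoot_numeric_error" (exit 3).

inputError <- function(msg, code = "E_INPUT") {
    stop(structure(class = c("webfoot_input_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1), code = code)))
}

numericError <- function(msg, code = "E_NUMERIC") {
    stop(structure(class = c("webfoot_numeric_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1), code = code)))
}
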