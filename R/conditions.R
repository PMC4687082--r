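# Structured error conditions so callers (and the CLI) can distinguish
# bad inputs (exit 2) from I/O failures (exit 3).

abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("hgt_validation_error", "hgt_error"),
                      call = call))
}

abort_parse <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("hgt_parse_error", "hgt_validation_error",
                                     "hgt_error"),
                      call = call))
}

abort_io <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("hgt_io_error", "hgt_error"), call = call))
}
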