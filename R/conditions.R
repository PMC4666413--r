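# Structured conditions: every user-facing failure mode raises an error of
# class c("pvs_error_<what>", "pvs_error", "error") so callers and tests can
# catch specific failures without string matching.
pvs_stop <- function(what, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("pvs_error_", what), "pvs_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
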