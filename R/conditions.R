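# Structured error conditions. Each condition carries a package prefix plus a
# specific class so callers can catch e.g. "brachysel_missing_tandem".

abort <- function(class, msg) {
  cond <- structure(
    list(message = msg, call = sys.call(-1)),
    class = c(paste0("brachysel_", class), "brachysel_error", "error", "condition")
  )
  stop(cond)
}

#' @noRd
warn_log <- function(msg) {
  warning(msg, call. = FALSE)
  invisible(msg)
}
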