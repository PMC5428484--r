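# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_msg <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

# classed condition so callers can distinguish "no annotation" from real errors
stop_unscorable <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("gofunsim_unscorable", "gofunsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

stop_gofunsim <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("gofunsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

is_unscorable <- function(e) inherits(e, "gofunsim_unscorable")

# 9 significant digits: round-trips the worked-example constants through TSV
format_score <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 9, format = "g")))
}

NAMESPACES <- c("BP", "MF", "CC")

OBO_NS_MAP <- c(biological_process = "BP",
                molecular_function = "MF",
                cellular_component = "CC")
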