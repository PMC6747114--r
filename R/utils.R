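`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats qnorm setNames
#' @importFrom utils head write.csv
NULL

# Observation window emulated by the synthetic stream (calendar year 2018, UTC).
.vs_period_start <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
.vs_period_end   <- as.POSIXct("2018-12-31 23:59:59", tz = "UTC")

vs_stop <- function(..., class = "vapescope_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) vs_stop(...)
  invisible(TRUE)
}

format_iso8601 <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out
}

# Stable order-independent hash of an R object (used for run logs).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # djb2 over the serialized payload; cheap and dependency-free
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
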