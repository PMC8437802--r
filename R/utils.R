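#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rgamma rpois runif setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

## Integer-safe coordinate check; coordinates are 0-based half-open everywhere
## inside the package, conversions happen only at format boundaries.
check_intervals <- function(start, end, what = "interval") {
  bad <- which(!(start < end))
  if (length(bad)) {
    stop(sprintf("%s %d has start >= end (%s >= %s)",
                 what, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

## deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * index) %% 2147483647)
}
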