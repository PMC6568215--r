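# Internal helpers: angle arithmetic, seeding, small validators.

# The namespace must import data.table for data.table-aware `[` semantics
# inside package code (cedta).
#' @importFrom data.table data.table as.data.table fread rbindlist setcolorder
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap an angle difference into (-180, 180]
#' @noRd
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Euclidean norm of point rows
#' @noRd
row_norm <- function(xy) sqrt(xy[, 1]^2 + xy[, 2]^2)

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cm_config_error", "cm_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cm_format_error", "cm_error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cm_validation_error", "cm_error")))
}

stop_capability <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cm_capability_error", "cm_error")))
}

#' Deterministic 31-bit substream seed from a root seed and string keys
#'
#' FNV-1a style accumulation over the utf-8 bytes of the keys, folded to a
#' non-negative value below 2^31 so it is always a valid [set.seed()] input.
#' Insertion-order independence of cohort simulation rests on this: the
#' substream depends only on (seed, subject, trial), never on loop order.
#' @noRd
substream_seed <- function(seed, ...) {
  keys <- paste(c(seed, ...), collapse = "\r")
  h <- 2166.0
  for (b in utf8ToInt(keys)) {
    h <- (h * 16777.0 + b) %% 2147483647
  }
  as.integer(floor(h))
}

#' Centered moving average with shrinking windows at the edges
#' @noRd
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
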