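#' Probability / value intervals with open or closed endpoints
#'
#' Small helper class used throughout the consistency checker. A
#' `p_interval` represents the set of values a printed number could have
#' stood for (rounding), or the set of p values admitted by a reported
#' comparison such as `p < .05`.
#'
#' @param lo,hi Interval endpoints, `lo <= hi`.
#' @param lo_closed,hi_closed Whether each endpoint belongs to the interval.
#' @return An object of class `p_interval`.
#' @examples
#' p_interval(0.0455, 0.0465, TRUE, FALSE) # printed "p = .046"
#' @export
p_interval <- function(lo, hi, lo_closed = TRUE, hi_closed = FALSE) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (is.na(lo) || is.na(hi) || lo > hi)
    stop("invalid interval: lo must be <= hi and finite")
  structure(list(lo = lo, hi = hi,
                 lo_closed = isTRUE(lo_closed), hi_closed = isTRUE(hi_closed)),
            class = "p_interval")
}

#' @export
print.p_interval <- function(x, ...) {
  cat(sprintf("%s%g, %g%s\n",
              if (x$lo_closed) "[" else "(", x$lo, x$hi,
              if (x$hi_closed) "]" else ")"))
  invisible(x)
}

#' Do two intervals share at least one point?
#'
#' Endpoint closures are honoured: `[0, .05)` and `[.05, 1]` do not
#' overlap, while `[0, .05]` and `[.05, 1]` do.
#'
#' @param a,b `p_interval` objects.
#' @return Logical scalar.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(inherits(a, "p_interval"), inherits(b, "p_interval"))
  left_ok <- a$lo < b$hi || (a$lo == b$hi && a$lo_closed && b$hi_closed)
  right_ok <- b$lo < a$hi || (b$lo == a$hi && b$lo_closed && a$hi_closed)
  left_ok && right_ok
}

#' Does an interval lie entirely below a threshold?
#'
#' Used for the significance filter: a result counts as "reported
#' significant" only when every value it could stand for is strictly
#' below the threshold (by default .05).
#'
#' @param a A `p_interval`.
#' @param x Threshold.
#' @return Logical scalar.
#' @export
interval_below <- function(a, x) {
  stopifnot(inherits(a, "p_interval"), is.numeric(x), length(x) == 1L)
  a$hi < x || (a$hi == x && !a$hi_closed)
}

# Scale an interval by a positive factor (used for the one-tailed salvage:
# a one-sided p is half the two-sided one).
scale_interval <- function(a, factor) {
  p_interval(a$lo * factor, a$hi * factor, a$lo_closed, a$hi_closed)
}
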