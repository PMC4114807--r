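#' Number of decimal places in a printed number
#'
#' Trailing zeros count: `"4.450"` has three decimals, and is therefore a
#' more precise claim than `"4.45"`.
#'
#' @param printed Character vector of printed decimal numbers.
#' @return Integer vector of decimal counts.
#' @keywords internal
n_decimals <- function(printed) {
  printed <- normalize_minus(printed)
  has_dot <- grepl(".", printed, fixed = TRUE)
  ifelse(has_dot, nchar(sub("^[^.]*\\.", "", printed)), 0L)
}

# Map typographic minus signs (U+2212, en dash) to ASCII hyphen.
normalize_minus <- function(x) {
  gsub("[−–]", "-", x)
}

#' Rounding interval of a printed decimal number
#'
#' A number printed with k decimals stands for any value in
#' `[v - u/2, v + u/2)` with `u = 10^-k`: all values that round to the
#' printed string under round-half-up.
#'
#' @param printed A single printed number as a character string
#'   (e.g. `"4.45"`, `"4.450"`, `"2"`, `"-2.50"`).
#' @return A [p_interval].
#' @examples
#' rounding_interval("4.45")  # [4.445, 4.455)
#' rounding_interval("4.450") # [4.4495, 4.4505)
#' @export
rounding_interval <- function(printed) {
  stopifnot(length(printed) == 1L)
  printed <- normalize_minus(as.character(printed))
  v <- suppressWarnings(as.numeric(printed))
  if (is.na(v) || !is.finite(v)) stop("not a finite printed number: ", printed)
  u <- 10^(-n_decimals(printed))
  p_interval(v - u / 2, v + u / 2, lo_closed = TRUE, hi_closed = FALSE)
}

#' Recompute a p value from a reported test statistic
#'
#' For a t statistic the two-tailed tail mass of the t distribution with
#' `df2` degrees of freedom at `|statistic|`; for an F statistic the upper
#' tail mass of the F distribution with `(df1, df2)` degrees of freedom.
#' Vectorised over all arguments.
#'
#' @param family `"t"` or `"F"` (recycled).
#' @param df1 Numerator degrees of freedom (ignored for t tests).
#' @param df2 (Denominator) degrees of freedom; may be fractional
#'   (Welch-corrected t tests are evaluated at the printed df).
#' @param statistic Numeric test statistic.
#' @return Numeric vector of p values in (0, 1].
#' @examples
#' recompute_p("F", 1, 23, 4.45)  # 0.046 to three decimals
#' recompute_p("t", NA, 23, 0)    # 1
#' @export
recompute_p <- function(family, df1, df2, statistic) {
  n <- max(length(family), length(df1), length(df2), length(statistic))
  family <- rep_len(as.character(family), n)
  df1 <- rep_len(as.numeric(df1), n)
  df2 <- rep_len(as.numeric(df2), n)
  statistic <- rep_len(as.numeric(statistic), n)
  if (any(!family %in% c("t", "F"))) stop("family must be 't' or 'F'")
  if (any(!is.finite(df2) | df2 <= 0)) stop("df2 must be finite and positive")
  if (any(!is.finite(statistic))) stop("statistic must be finite")
  is_t <- family == "t"
  if (any(!is_t & (!is.finite(df1) | df1 < 1)))
    stop("df1 must be >= 1 for F tests")
  if (any(!is_t & statistic < 0)) stop("F statistic must be non-negative")
  p <- numeric(n)
  p[is_t] <- 2 * stats::pt(-abs(statistic[is_t]), df2[is_t])
  p[!is_t] <- stats::pf(statistic[!is_t], df1[!is_t], df2[!is_t],
                        lower.tail = FALSE)
  p
}

#' Interval of p values admitted by a reported p
#'
#' `p = .046` admits the rounding interval of the printed string (clipped
#' to the unit interval); `p < x` admits `(0, x)`; `p > x` admits `(x, 1]`.
#'
#' @param comparator `"eq"`, `"lt"` or `"gt"`.
#' @param p_text Printed p value as a string, parsing into (0, 1).
#' @return A [p_interval].
#' @export
reported_p_interval <- function(comparator, p_text) {
  v <- suppressWarnings(as.numeric(p_text))
  if (is.na(v) || v <= 0 || v >= 1) stop("p out of range: ", p_text)
  switch(comparator,
    eq = {
      iv <- rounding_interval(p_text)
      lo <- max(iv$lo, 0)
      hi <- min(iv$hi, 1)
      p_interval(lo, hi,
                 lo_closed = iv$lo_closed && iv$lo >= 0,
                 hi_closed = iv$hi_closed && iv$hi <= 1)
    },
    lt = p_interval(0, v, lo_closed = FALSE, hi_closed = FALSE),
    gt = p_interval(v, 1, lo_closed = FALSE, hi_closed = TRUE),
    stop("unknown comparator: ", comparator)
  )
}

# Image of the statistic's rounding interval under the p mapping.
# The p value is strictly decreasing in |statistic| for both families, so
# the image of an interval of statistics is again an interval; endpoint
# closures follow the statistic endpoints through the (continuous) map.
statistic_p_interval <- function(family, df1, df2, statistic_text) {
  iv <- rounding_interval(statistic_text)
  if (family == "F") iv$lo <- max(iv$lo, 0)
  if (iv$lo <= 0 && iv$hi >= 0 && family == "t") {
    # interval straddles zero: p attains 1 at statistic 0 (interior point)
    p_at_lo <- recompute_p(family, df1, df2, iv$lo)
    p_at_hi <- recompute_p(family, df1, df2, iv$hi)
    if (p_at_lo <= p_at_hi)
      p_interval(p_at_lo, 1, lo_closed = iv$lo_closed, hi_closed = TRUE)
    else
      p_interval(p_at_hi, 1, lo_closed = iv$hi_closed, hi_closed = TRUE)
  } else {
    a <- min(abs(iv$lo), abs(iv$hi))  # |statistic| at weakest evidence? no:
    b <- max(abs(iv$lo), abs(iv$hi))
    # map: small |s| -> large p. Which original endpoint supplies a and b?
    lo_is_small <- abs(iv$lo) <= abs(iv$hi)
    small_closed <- if (lo_is_small) iv$lo_closed else iv$hi_closed
    big_closed <- if (lo_is_small) iv$hi_closed else iv$lo_closed
    p_interval(recompute_p(family, df1, df2, b),
               recompute_p(family, df1, df2, a),
               lo_closed = big_closed, hi_closed = small_closed)
  }
}

#' Classify a reporting error
#'
#' An inconsistent result is an error. It is a *large* error when the
#' reported and recomputed p differ by more than .01, and a *gross* error
#' when a result reported as significant (entirely below .05) recomputes
#' to a non-significant p (>= .05). Both flags are subsets of the error
#' class; a consistent result carries no flags.
#'
#' @param p_recomputed Point recomputation from the printed statistic.
#' @param reported_interval A [p_interval] for the reported p.
#' @param consistent Verdict from the interval-overlap rule.
#' @param p_reported_point Point value of the reported p: the printed
#'   value for `eq`, the bound for `lt`/`gt`.
#' @return A list with `error_class` (`"none"`/`"error"`), `is_large`,
#'   `is_gross`.
#' @export
classify_error <- function(p_recomputed, reported_interval, consistent,
                           p_reported_point) {
  if (consistent)
    return(list(error_class = "none", is_large = FALSE, is_gross = FALSE))
  list(
    error_class = "error",
    is_large = abs(p_reported_point - p_recomputed) > 0.01,
    is_gross = interval_below(reported_interval, 0.05) && p_recomputed >= 0.05
  )
}

#' Check reported p values against recomputation, rounding-aware
#'
#' For each result the printed statistic's rounding interval is propagated
#' through the (monotone) p mapping, and the result is *consistent* when
#' that interval of achievable p values overlaps the interval admitted by
#' the reported p. Inconsistent results flagged as arising in a one-tailed
#' context are salvaged when halving the recomputed interval restores
#' overlap (a one-sided p is half the two-sided one); salvaged results are
#' counted as consistent but marked.
#'
#' @param results A results data frame as returned by [scan_text()] or
#'   [read_manual_results()].
#' @param one_tailed_salvage Apply the one-tailed salvage rule (default
#'   `TRUE`); set `FALSE` for a strict check.
#' @return `results` with columns `p_recomputed`, `consistent`,
#'   `one_tailed_salvage`, `error_class`, `is_large`, `is_gross` appended.
#' @examples
#' r <- scan_text("F(1,23) = 4.45, p = .046")
#' check_consistency(r)$consistent  # TRUE
#' @export
check_consistency <- function(results, one_tailed_salvage = TRUE) {
  stopifnot(is.data.frame(results))
  n <- nrow(results)
  p_rec <- numeric(n)
  consistent <- logical(n)
  salvage <- logical(n)
  error_class <- character(n)
  is_large <- logical(n)
  is_gross <- logical(n)
  for (i in seq_len(n)) {
    fam <- results$test_family[i]
    df1 <- results$df1[i]
    df2 <- results$df2[i]
    stat_text <- results$statistic_text[i]
    p_rec[i] <- recompute_p(fam, df1, df2,
                            as.numeric(normalize_minus(stat_text)))
    p_iv <- statistic_p_interval(fam, df1, df2, stat_text)
    rep_iv <- reported_p_interval(results$p_comparator[i], results$p_text[i])
    ok <- intervals_overlap(p_iv, rep_iv)
    if (!ok && one_tailed_salvage &&
        identical(results$tail_note[i], "one_tailed_context") &&
        intervals_overlap(scale_interval(p_iv, 0.5), rep_iv)) {
      ok <- TRUE
      salvage[i] <- TRUE
    }
    consistent[i] <- ok
    point <- as.numeric(results$p_text[i])
    cls <- classify_error(p_rec[i], rep_iv, ok, point)
    error_class[i] <- cls$error_class
    is_large[i] <- cls$is_large
    is_gross[i] <- cls$is_gross
  }
  results$p_recomputed <- p_rec
  results$consistent <- consistent
  results$one_tailed_salvage <- salvage
  results$error_class <- error_class
  results$is_large <- is_large
  results$is_gross <- is_gross
  results
}
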