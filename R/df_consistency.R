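#' Expected t-test degrees of freedom for a described design
#'
#' For an independent two-sample t test the df equal the effective sample
#' size minus 2; for a paired or one-sample test, minus 1. The effective
#' sample size is the described total minus any *reported* exclusions and
#' missing values — only undisclosed removals should produce a
#' discrepancy.
#'
#' @param design `"independent_two_sample"`, `"paired_or_one_sample"`, or
#'   `"unknown"` (vectorised).
#' @param n_total Described total sample size.
#' @param exclusions,missing Reported counts of excluded and missing
#'   cases (default 0).
#' @return Integer vector; `NA` where the design is unknown.
#' @examples
#' expected_df("independent_two_sample", 40)      # 38
#' expected_df("paired_or_one_sample", 25, missing = 2)  # 22
#' @export
expected_df <- function(design, n_total, exclusions = 0, missing = 0) {
  n <- max(length(design), length(n_total), length(exclusions),
           length(missing))
  design <- rep_len(design, n)
  n_total <- rep_len(n_total, n)
  exclusions <- rep_len(exclusions, n)
  missing <- rep_len(missing, n)
  bad <- !design %in% c("independent_two_sample", "paired_or_one_sample",
                        "unknown")
  if (any(bad)) stop("unknown design label: ", design[bad][1])
  n_eff <- n_total - exclusions - missing
  out <- rep(NA_integer_, n)
  two <- design == "independent_two_sample"
  one <- design == "paired_or_one_sample"
  out[two] <- as.integer(n_eff[two] - 2)
  out[one] <- as.integer(n_eff[one] - 1)
  out
}

#' Compare a reported t-test df with its expected value
#'
#' The screen is conservative: fractional (Welch-corrected) dfs and
#' unknown designs are `"indeterminate"`, never a discrepancy, because
#' the N-minus-2 rule does not apply to them. Integer dfs must match
#' exactly — any mismatch is a candidate for undisclosed exclusion of
#' cases (or unreported missingness, or a misprinted df; the screen
#' cannot tell these apart).
#'
#' @param df2 Reported df of the t test (vectorised).
#' @param expected Expected df from [expected_df()] (recycled).
#' @return Character vector: `"match"`, `"discrepancy"`, or
#'   `"indeterminate"`.
#' @export
check_t_df <- function(df2, expected) {
  n <- max(length(df2), length(expected))
  df2 <- rep_len(as.numeric(df2), n)
  expected <- rep_len(expected, n)
  out <- rep("indeterminate", n)
  eligible <- !is.na(expected) & is.finite(df2) & df2 == round(df2)
  out[eligible & df2 == expected] <- "match"
  out[eligible & df2 != expected] <- "discrepancy"
  out
}

#' Screen an article's t tests against described sample sizes
#'
#' Each t test with an integer df is compared against the expected df of
#' its study. When the results carry a `study` column the comparison is
#' against that study alone; otherwise a df is a `"match"` if it matches
#' the expected df of *any* described study with known design (the
#' benefit-of-the-doubt rule an article-level audit needs when results
#' cannot be attributed to studies).
#'
#' @param results Results data frame for one article (rows with
#'   `test_family == "t"` are screened; others ignored). An optional
#'   `study` column (integer index into `studies`) pins each result to a
#'   study.
#' @param studies Data frame of the article's described studies with
#'   columns `design`, `n_total` and optionally `exclusions`, `missing`.
#' @return `results` restricted to t tests, with a `df_verdict` column.
#' @export
screen_t_dfs <- function(results, studies) {
  stopifnot(is.data.frame(results), is.data.frame(studies))
  t_res <- results[results$test_family == "t", , drop = FALSE]
  if (!nrow(t_res)) {
    t_res$df_verdict <- character(0)
    return(t_res)
  }
  if (!"exclusions" %in% names(studies)) studies$exclusions <- 0
  if (!"missing" %in% names(studies)) studies$missing <- 0
  exp_df <- expected_df(studies$design, studies$n_total,
                        studies$exclusions, studies$missing)
  verdict <- character(nrow(t_res))
  has_study <- "study" %in% names(t_res)
  for (i in seq_len(nrow(t_res))) {
    df2 <- t_res$df2[i]
    if (has_study && !is.na(t_res$study[i])) {
      verdict[i] <- check_t_df(df2, exp_df[t_res$study[i]])
    } else if (all(is.na(exp_df)) || df2 != round(df2)) {
      verdict[i] <- "indeterminate"
    } else {
      known <- exp_df[!is.na(exp_df)]
      verdict[i] <- if (any(known == df2)) "match" else "discrepancy"
    }
  }
  t_res$df_verdict <- verdict
  t_res
}

#' Article-level df-discrepancy flag
#'
#' An article is flagged when at least one of its t tests has a df
#' inconsistent with the described sample sizes — the signature of
#' undisclosed data exclusion.
#'
#' @param verdicts Character vector of per-test verdicts from
#'   [check_t_df()] or [screen_t_dfs()].
#' @return List with `flag` (`TRUE`/`FALSE`, or `NA` when no t test was
#'   determinate) and `counts` (named vector over the three verdicts).
#' @export
article_discrepancy <- function(verdicts) {
  counts <- c(match = sum(verdicts == "match"),
              discrepancy = sum(verdicts == "discrepancy"),
              indeterminate = sum(verdicts == "indeterminate"))
  flag <- if (counts["match"] + counts["discrepancy"] == 0) NA
    else unname(counts["discrepancy"] > 0)
  list(flag = flag, counts = counts)
}
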