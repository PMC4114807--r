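#' @title Extraction of APA-style t and F test results from article text
#' @description Internal regular expression for completely reported results.
#'   Only complete triplets (statistic, dfs, p value) are matched: a fragment
#'   lacking any of the three never yields a result. Recognised dialects:
#'   optional italics markers (`*t*`, `*p*`), flexible whitespace, en-dash or
#'   Unicode minus for the sign, optional leading zero in the p value, and a
#'   bare `ns` in place of the p clause (captured as `p > .05`).
#' @keywords internal
#' @name extraction-internal
NULL

apa_pattern <- paste0(
  "(?<![A-Za-z])\\*?([tF])\\*?\\s*",          # 1: family
  "\\(\\s*(?:(\\d+)\\s*,\\s*)?",              # 2: df1 (F only)
  "(\\d+(?:\\.\\d+)?)\\s*\\)",                # 3: df2
  "\\s*=\\s*",
  "([-−–]?\\s?(?:\\d+\\.?\\d*|\\.\\d+))", # 4: statistic
  "\\s*,\\s*",
  "(?:\\*?p\\*?\\s*([=<>])\\s*(0?\\.\\d+)",   # 5: comparator, 6: p value
  "|(ns)\\b)"                                 # 7: 'ns' shorthand
)

empty_results <- function() {
  data.frame(
    article_id = character(0), test_family = character(0),
    df1 = numeric(0), df2 = numeric(0), statistic_text = character(0),
    p_comparator = character(0), p_text = character(0),
    span_start = integer(0), span_end = integer(0),
    source = character(0), tail_note = character(0),
    stringsAsFactors = FALSE
  )
}

#' Scan article text for APA-style t and F test results
#'
#' Finds every completely reported t or F test — test statistic, degrees of
#' freedom, and p value — written in APA style, e.g.
#' `"F(1, 23) = 4.45, p = .046"` or `"*t*(40) = −2.50, *p* < .05"`.
#' Printed precision is preserved: statistic and p value are returned as the
#' strings that appeared in the text (trailing zeros intact), so that
#' rounding-aware consistency checks can reconstruct exactly what was
#' claimed. Fragments missing the statistic, the dfs, or the p value are
#' skipped. A window around each match (default 100 characters each side) is
#' searched for "one-tailed"/"one-sided" and matches in such a context are
#' flagged, because a one-sided test would otherwise look like a reporting
#' error.
#'
#' @param text Article body as a single character string, or a one-row
#'   document data frame with columns `article_id` and `text`.
#' @param article_id Identifier attached to the results (default `NA`).
#' @param tail_window Characters searched on each side of a match for
#'   one-tailed context.
#' @return A data frame with one row per result and columns `article_id`,
#'   `test_family`, `df1`, `df2`, `statistic_text`, `p_comparator`,
#'   `p_text`, `span_start`, `span_end`, `source`, `tail_note`. Spans are
#'   1-based inclusive character offsets, non-overlapping and in text order.
#' @examples
#' scan_text("We found F(1,23) = 4.45, p = .046 for the interaction.")
#' @export
scan_text <- function(text, article_id = NA_character_, tail_window = 100L) {
  if (is.data.frame(text)) {
    stopifnot(nrow(text) == 1L)
    article_id <- text$article_id
    text <- text$text
  }
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- gregexpr(apa_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_results())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(i, j) {
    if (cs[i, j] == 0L) NA_character_
    else substr(text, cs[i, j], cs[i, j] + cl[i, j] - 1L)
  }
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    family <- grab(i, 1L)
    df1_txt <- grab(i, 2L)
    df2_txt <- grab(i, 3L)
    stat <- gsub("\\s", "", normalize_minus(grab(i, 4L)))
    is_ns <- !is.na(grab(i, 7L))
    comparator <- if (is_ns) "gt"
      else switch(grab(i, 5L), "=" = "eq", "<" = "lt", ">" = "gt")
    p_text <- if (is_ns) ".05" else grab(i, 6L)
    # completeness and validity filters
    if (family == "F" && is.na(df1_txt)) next  # F needs both dfs
    if (family == "t" && !is.na(df1_txt)) next # t has a single df
    p_val <- as.numeric(p_text)
    if (is.na(p_val) || p_val <= 0 || p_val >= 1) next
    if (!is.finite(as.numeric(stat))) next
    if (family == "F" && as.numeric(stat) < 0) next
    win_lo <- max(1L, starts[i] - tail_window)
    win_hi <- min(nchar(text), starts[i] + lens[i] - 1L + tail_window)
    ctx <- substr(text, win_lo, win_hi)
    tail_note <- if (grepl("one[- ]?(tailed|sided)", ctx, ignore.case = TRUE))
      "one_tailed_context" else "none"
    rows[[i]] <- data.frame(
      article_id = article_id, test_family = family,
      df1 = if (is.na(df1_txt)) NA_real_ else as.numeric(df1_txt),
      df2 = as.numeric(df2_txt),
      statistic_text = stat, p_comparator = comparator, p_text = p_text,
      span_start = starts[i], span_end = starts[i] + lens[i] - 1L,
      source = "auto", tail_note = tail_note,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_results())
  do.call(rbind, rows)
}

#' Scan every document in a corpus
#'
#' @param documents Data frame with columns `article_id` and `text` (one
#'   row per article), as produced by [generate_corpus()] or
#'   [read_corpus_dir()].
#' @param tail_window Passed to [scan_text()].
#' @return Row-bound results of [scan_text()] over all documents.
#' @export
scan_corpus <- function(documents, tail_window = 100L) {
  stopifnot(is.data.frame(documents),
            all(c("article_id", "text") %in% names(documents)),
            !anyDuplicated(documents$article_id))
  out <- lapply(seq_len(nrow(documents)), function(i)
    scan_text(documents$text[i], documents$article_id[i], tail_window))
  do.call(rbind, c(out, list(empty_results())))
}

#' Render a result in APA style
#'
#' Inverse of [scan_text()] up to character spans: scanning a rendered
#' result recovers every field, including printed precision. Style
#' variants exercise the scanner's dialects and are used by the synthetic
#' corpus generator.
#'
#' @param r One-row results data frame (fields as in [scan_text()]'s
#'   return value).
#' @param style `"canonical"` (`"F(1, 23) = 4.45, p = .046"`),
#'   `"italics"` (asterisk-marked `*F*`/`*p*`), or `"tight"` (no optional
#'   spaces).
#' @return A character string.
#' @examples
#' r <- scan_text("t(23) = 2.11, p = .046")
#' render_result(r)
#' @export
render_result <- function(r, style = c("canonical", "italics", "tight")) {
  style <- match.arg(style)
  stopifnot(is.data.frame(r), nrow(r) == 1L)
  op <- switch(r$p_comparator, eq = "=", lt = "<", gt = ">")
  dfs <- if (r$test_family == "F") {
    paste0(format_df(r$df1), if (style == "tight") "," else ", ",
           format_df(r$df2))
  } else format_df(r$df2)
  switch(style,
    canonical = sprintf("%s(%s) = %s, p %s %s",
                        r$test_family, dfs, r$statistic_text, op, r$p_text),
    italics = sprintf("*%s*(%s) = %s, *p* %s %s",
                      r$test_family, dfs, r$statistic_text, op, r$p_text),
    tight = sprintf("%s(%s)=%s, p%s%s",
                    r$test_family, dfs, r$statistic_text, op, r$p_text)
  )
}

format_df <- function(df) {
  if (df == round(df)) format(as.integer(df)) else format(df)
}

#' Read a manually entered results table
#'
#' Results that are not reported in APA style (for example because an
#' effect size sits between the statistic and the p value) cannot be
#' scanned reliably; they are entered by hand in a CSV with columns
#' `article_id`, `test_family`, `df1`, `df2`, `statistic_text`,
#' `p_comparator`, `p_text` (and optionally `tail_note`). Every row is
#' validated; a malformed row rejects the whole file with its row number
#' and the reason.
#'
#' @param path Path to the CSV file.
#' @return A results data frame (`source = "manual"`, spans `NA`).
#' @export
read_manual_results <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("article_id", "test_family", "df1", "df2",
                "statistic_text", "p_comparator", "p_text")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("manual results file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) return(empty_results())
  bad <- function(i, why) stop(sprintf("row %d: %s", i, why))
  for (i in seq_len(nrow(tab))) {
    fam <- tab$test_family[i]
    if (!fam %in% c("t", "F")) bad(i, paste("unknown test family", fam))
    df1 <- suppressWarnings(as.numeric(tab$df1[i]))
    df2 <- suppressWarnings(as.numeric(tab$df2[i]))
    if (fam == "F" && (is.na(df1) || df1 < 1)) bad(i, "F test needs df1 >= 1")
    if (fam == "t" && !is.na(df1)) bad(i, "t test must not carry df1")
    if (is.na(df2) || df2 <= 0) bad(i, "df2 must be positive")
    s <- suppressWarnings(as.numeric(normalize_minus(tab$statistic_text[i])))
    if (is.na(s) || !is.finite(s)) bad(i, "statistic not a finite number")
    if (fam == "F" && s < 0) bad(i, "F statistic must be non-negative")
    if (!tab$p_comparator[i] %in% c("eq", "lt", "gt"))
      bad(i, paste("unknown comparator", tab$p_comparator[i]))
    p <- suppressWarnings(as.numeric(tab$p_text[i]))
    if (is.na(p) || p <= 0 || p >= 1) bad(i, "p out of range")
  }
  data.frame(
    article_id = tab$article_id, test_family = tab$test_family,
    df1 = suppressWarnings(as.numeric(tab$df1)),
    df2 = suppressWarnings(as.numeric(tab$df2)),
    statistic_text = normalize_minus(tab$statistic_text),
    p_comparator = tab$p_comparator, p_text = tab$p_text,
    span_start = NA_integer_, span_end = NA_integer_,
    source = "manual",
    tail_note = if ("tail_note" %in% names(tab)) tab$tail_note else "none",
    stringsAsFactors = FALSE
  )
}
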