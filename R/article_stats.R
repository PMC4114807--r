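#' Significance inclusion filter
#'
#' Only results reported as significant enter the article-level analyses:
#' the reported p interval must lie entirely below .05. A printed
#' `p = .046` qualifies (its rounding interval tops out at .0465);
#' `p = .05` does not (its interval straddles .05); `p < .05` does
#' (every admitted value is strictly below the bound). Results reported
#' with `>` are never included.
#'
#' @param results Results data frame.
#' @param alpha Significance threshold (default .05).
#' @return Logical vector, one flag per row.
#' @export
include_result <- function(results, alpha = 0.05) {
  vapply(seq_len(nrow(results)), function(i) {
    iv <- reported_p_interval(results$p_comparator[i], results$p_text[i])
    interval_below(iv, alpha)
  }, logical(1))
}

# Parse semicolon-joined per-study metadata fields into a list of
# per-article study tables.
parse_studies <- function(metadata) {
  split_num <- function(x) as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
  split_chr <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]
  out <- vector("list", nrow(metadata))
  names(out) <- metadata$article_id
  for (i in seq_len(nrow(metadata))) {
    n_total <- split_num(metadata$sample_sizes[i])
    k <- length(n_total)
    design <- if ("designs" %in% names(metadata) &&
                  nzchar(metadata$designs[i]))
      split_chr(metadata$designs[i]) else rep("unknown", k)
    excl <- if ("exclusions" %in% names(metadata) &&
                nzchar(metadata$exclusions[i]))
      split_num(metadata$exclusions[i]) else rep(0, k)
    miss <- if ("missing" %in% names(metadata) &&
                nzchar(metadata$missing[i]))
      split_num(metadata$missing[i]) else rep(0, k)
    stopifnot(length(design) == k, length(excl) == k, length(miss) == k)
    out[[i]] <- data.frame(study = seq_len(k), design = design,
                           n_total = n_total, exclusions = excl,
                           missing = miss, stringsAsFactors = FALSE)
  }
  out
}

#' Reduce checked results to article-level records
#'
#' Applies the significance inclusion rule, then computes per article the
#' number of included (significant) results, the median of their
#' recomputed p values, error counts (any, large, gross), and the median
#' of the described study sample sizes. Articles with no included result
#' are dropped (with a message) — they would not have entered the sample.
#' When the metadata carries per-study designs, reported t-test dfs are
#' screened against sample sizes and an article-level discrepancy flag is
#' added.
#'
#' @param results Results data frame with consistency columns (from
#'   [check_consistency()]).
#' @param metadata Article metadata data frame: `article_id`, `group`,
#'   `journal`, `sample_sizes` (semicolon-joined), optionally `designs`,
#'   `exclusions`, `missing` (semicolon-joined, parallel to
#'   `sample_sizes`).
#' @param screen_dfs Run the df-vs-sample-size screen (default `TRUE`
#'   when designs are available).
#' @return Data frame, one row per retained article: `article_id`,
#'   `group`, `journal`, `n_results`, `n_significant`,
#'   `median_recomputed_p`, `n_error`, `n_large`, `n_gross`,
#'   `median_sample_size`, `df_flag`, `df_n_discrepant`. The dropped
#'   article ids are attached as attribute `"dropped"`.
#' @export
summarize_articles <- function(results, metadata,
                               screen_dfs = "designs" %in% names(metadata)) {
  stopifnot(is.data.frame(results), is.data.frame(metadata),
            !anyDuplicated(metadata$article_id))
  needed <- c("p_recomputed", "consistent", "error_class")
  if (!all(needed %in% names(results)))
    stop("results must first pass through check_consistency()")
  studies <- parse_studies(metadata)
  rows <- vector("list", nrow(metadata))
  dropped <- character(0)
  for (i in seq_len(nrow(metadata))) {
    id <- metadata$article_id[i]
    res <- results[results$article_id == id, , drop = FALSE]
    inc <- res[include_result(res), , drop = FALSE]
    if (!nrow(inc)) {
      dropped <- c(dropped, id)
      next
    }
    df_flag <- NA
    df_n_disc <- NA_integer_
    if (screen_dfs) {
      screened <- screen_t_dfs(res, studies[[id]])
      ad <- article_discrepancy(screened$df_verdict)
      df_flag <- ad$flag
      df_n_disc <- unname(ad$counts["discrepancy"])
    }
    rows[[i]] <- data.frame(
      article_id = id, group = metadata$group[i],
      journal = metadata$journal[i],
      n_results = nrow(res), n_significant = nrow(inc),
      median_recomputed_p = stats::median(inc$p_recomputed),
      n_error = sum(inc$error_class == "error"),
      n_large = sum(inc$is_large),
      n_gross = sum(inc$is_gross),
      median_sample_size = stats::median(studies[[id]]$n_total),
      df_flag = df_flag, df_n_discrepant = df_n_disc,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped))
    message(length(dropped),
            " article(s) dropped (no result reported as significant): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "dropped") <- dropped
  out
}

#' Group-by-journal error tallies
#'
#' Counts statistics and errors per group and journal, plus a totals row
#' per group: number of articles, number of (significant) statistics,
#' error counts, and numbers of articles with at least one error / large
#' error / gross error, with the corresponding percentages.
#'
#' @param articles Article-level data frame from [summarize_articles()].
#' @return Data frame with one row per group-journal cell and one
#'   `"Total"` row per group. Column sums across journals equal the
#'   totals row within each group.
#' @export
tally_groups <- function(articles) {
  stopifnot(is.data.frame(articles), nrow(articles) >= 1)
  cell <- function(sub, group, journal) {
    data.frame(
      group = group, journal = journal,
      n_articles = nrow(sub),
      n_statistics = sum(sub$n_significant),
      n_error = sum(sub$n_error),
      n_large = sum(sub$n_large),
      n_gross = sum(sub$n_gross),
      n_articles_error = sum(sub$n_error > 0),
      n_articles_large = sum(sub$n_large > 0),
      n_articles_gross = sum(sub$n_gross > 0),
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (g in unique(articles$group)) {
    ga <- articles[articles$group == g, , drop = FALSE]
    for (j in unique(ga$journal))
      out[[length(out) + 1L]] <-
        cell(ga[ga$journal == j, , drop = FALSE], g, j)
    out[[length(out) + 1L]] <- cell(ga, g, "Total")
  }
  tal <- do.call(rbind, out)
  tal$pct_error <- round(100 * tal$n_error / tal$n_statistics, 1)
  tal$pct_large <- round(100 * tal$n_large / tal$n_statistics, 1)
  tal$pct_gross <- round(100 * tal$n_gross / tal$n_statistics, 1)
  tal$pct_articles_error <- round(100 * tal$n_articles_error / tal$n_articles)
  tal$pct_articles_large <- round(100 * tal$n_articles_large / tal$n_articles)
  tal$pct_articles_gross <- round(100 * tal$n_articles_gross / tal$n_articles)
  tal
}
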