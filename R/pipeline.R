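#' Run the full reporting-quality pipeline on a corpus
#'
#' Scans every document for APA-style t and F results, appends manually
#' entered results if supplied, checks each result for consistency with
#' its recomputed p value, screens t-test dfs against described sample
#' sizes (when the metadata carries designs), reduces to article-level
#' records, and tallies errors by group and journal.
#'
#' @param documents Data frame with `article_id`, `text` (one article per
#'   row).
#' @param metadata Article metadata (see [summarize_articles()]).
#' @param manual_results Optional results data frame from
#'   [read_manual_results()].
#' @param one_tailed_salvage Passed to [check_consistency()].
#' @return List with `results` (per-result rows with verdicts and an
#'   `included` flag), `articles` (article-level records), `tallies`
#'   (group-by-journal error tallies), and `dropped` (articles with no
#'   significant result).
#' @examples
#' corpus <- generate_corpus(synthetic_spec(
#'   n_articles = c(outliers_removed = 4, no_removal = 3)), seed = 7)
#' out <- analyze_corpus(corpus$documents, corpus$metadata)
#' out$tallies
#' @export
analyze_corpus <- function(documents, metadata, manual_results = NULL,
                           one_tailed_salvage = TRUE) {
  results <- scan_corpus(documents)
  if (!is.null(manual_results)) results <- rbind(results, manual_results)
  results <- check_consistency(results,
                               one_tailed_salvage = one_tailed_salvage)
  results$included <- include_result(results)
  articles <- summarize_articles(results, metadata)
  list(results = results, articles = articles,
       tallies = tally_groups(articles),
       dropped = attr(articles, "dropped"))
}

#' Read a corpus directory
#'
#' Expects one UTF-8 plain-text file per article named
#' `<article_id>.txt` and a `metadata.csv` with columns `article_id`,
#' `group`, `journal`, `sample_sizes` (semicolon-joined integers) and
#' optionally `designs`, `exclusions`, `missing`.
#'
#' @param dir Directory path.
#' @return List with `documents` and `metadata` data frames.
#' @export
read_corpus_dir <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir)
  metadata <- utils::read.csv(meta_path, colClasses = "character",
                              stringsAsFactors = FALSE)
  stopifnot(all(c("article_id", "group", "journal", "sample_sizes") %in%
                  names(metadata)))
  texts <- vapply(metadata$article_id, function(id) {
    f <- file.path(dir, paste0(id, ".txt"))
    if (!file.exists(f)) stop("missing article file: ", f)
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1))
  documents <- data.frame(article_id = metadata$article_id, text = texts,
                          group = metadata$group,
                          journal = metadata$journal,
                          stringsAsFactors = FALSE, row.names = NULL)
  list(documents = documents, metadata = metadata)
}

#' Write a corpus to a directory
#'
#' Inverse of [read_corpus_dir()]: one text file per article plus
#' `metadata.csv` (and `ground_truth.csv` when generated ground truth is
#' supplied).
#'
#' @param corpus List with `documents`, `metadata`, optionally
#'   `ground_truth` (as from [generate_corpus()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_dir <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$documents)))
    writeLines(corpus$documents$text[i],
               file.path(dir, paste0(corpus$documents$article_id[i],
                                     ".txt")),
               useBytes = FALSE)
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  if (!is.null(corpus$ground_truth))
    utils::write.csv(corpus$ground_truth$results,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
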