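#' Specification of a synthetic article corpus
#'
#' Bundles every generator knob with defaults that emulate the corpus
#' structure the analysis pipeline expects: two article groups
#' (`outliers_removed`, 92 articles, and `no_removal`, 61), per-article
#' counts of significant results following a zero-truncated negative
#' binomial law with group means 19.4 and 14.5 (medians land within 2 of
#' 14 and 12), right-skewed significant p values arising mechanistically
#' from drawn effect sizes and sample sizes, reporting errors injected at
#' configurable per-result rates, and undisclosed case deletions (df
#' deficits) injected into 41% of articles.
#'
#' @param n_articles Named integer vector: articles per group.
#' @param results_mean Named numeric vector: mean results per article
#'   per group (negative binomial, zero-truncated).
#' @param results_dispersion Negative binomial size parameter of the
#'   results-per-article law.
#' @param journals Journal tags to sample from.
#' @param n_studies_max Studies per article are uniform on
#'   `1:n_studies_max`.
#' @param effect_meanlog,effect_sdlog Log-normal law of the true
#'   standardized effect size behind each result.
#' @param n_meanlog,n_sdlog,n_min Log-normal law (and floor) of the
#'   per-study total sample size.
#' @param prop_t Probability that a result is a t test (the first result
#'   of each article is always a t test so the df screen has material).
#' @param sig_filter Keep only results whose true p is below .05
#'   (mirrors the inclusion rule of the analysis).
#' @param error_rates Named vector `c(small=, large=, gross=)` of
#'   per-result injection probabilities. `small` errors are inconsistent
#'   but within .01 of the truth; `large` exceed .01; `gross` report a
#'   truly non-significant result as significant.
#' @param exclusion_rate Fraction of articles given an undisclosed df
#'   deficit.
#' @param deficit_max Deficits are uniform on `1:deficit_max` cases.
#' @param one_tailed_rate Fraction of clean t results reported with a
#'   halved (one-sided) p value and a "one-tailed" remark in the prose.
#' @param effect_scale Named numeric vector: multiplier on drawn effect
#'   sizes per group (a group difference in the p distribution).
#' @param error_mult Named numeric vector: multiplier on error rates per
#'   group.
#' @param seed Optional integer seed used by [generate_corpus()].
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_articles = c(outliers_removed = 92,
                                          no_removal = 61),
                           results_mean = c(outliers_removed = 19.4,
                                            no_removal = 14.5),
                           results_dispersion = 1.4,
                           journals = c("JESP", "CD", "CP", "JADP",
                                        "JECP", "JPSP"),
                           n_studies_max = 3,
                           effect_meanlog = log(0.55), effect_sdlog = 0.5,
                           n_meanlog = log(82), n_sdlog = 0.55, n_min = 10,
                           prop_t = 0.5,
                           sig_filter = TRUE,
                           error_rates = c(small = 0.04, large = 0.01,
                                           gross = 0.012),
                           exclusion_rate = 0.41, deficit_max = 3,
                           one_tailed_rate = 0,
                           effect_scale = c(outliers_removed = 1,
                                            no_removal = 1),
                           error_mult = c(outliers_removed = 1,
                                          no_removal = 1),
                           seed = NULL) {
  stopifnot(length(n_articles) == 2, all(n_articles >= 1),
            identical(names(n_articles), names(results_mean)),
            all(error_rates >= 0), all(error_rates <= 1),
            exclusion_rate >= 0, exclusion_rate <= 1,
            one_tailed_rate >= 0, one_tailed_rate <= 1,
            results_dispersion > 0)
  if (sum(error_rates) * max(error_mult) + one_tailed_rate > 1)
    stop("injection rates compose to more than 1")
  structure(as.list(environment()), class = "synthetic_spec")
}

# ---- small helpers ---------------------------------------------------------

format_p_text <- function(p, digits = 3) {
  sub("^0", "", sprintf(paste0("%.", digits, "f"), p))
}

format_stat_text <- function(x) sprintf("%.2f", x)

# zero-truncated negative binomial draw
rztnb <- function(n, mu, size) {
  out <- stats::rnbinom(n, mu = mu, size = size)
  while (any(out == 0))
    out[out == 0] <- stats::rnbinom(sum(out == 0), mu = mu, size = size)
  out
}

one_result_row <- function(article_id, study, family, df1, df2,
                           statistic_text, p_comparator, p_text) {
  data.frame(article_id = article_id, test_family = family,
             df1 = df1, df2 = df2, statistic_text = statistic_text,
             p_comparator = p_comparator, p_text = p_text,
             span_start = NA_integer_, span_end = NA_integer_,
             source = "auto", tail_note = "none", study = study,
             stringsAsFactors = FALSE)
}

# verdict of a single candidate result (classification only)
verdict_of <- function(row, tail_note = "none") {
  row$tail_note <- tail_note
  row$study <- NULL
  check_consistency(row)
}

#' Perturb a reported p value to create a known reporting error
#'
#' Given a correctly reported result, rewrites the p value so that the
#' consistency checker must flag it with exactly the requested class:
#' `"small"` (inconsistent, but within .01 of the recomputed p),
#' `"large"` (off by more than .01), or `"gross"` (a truly
#' non-significant result reported as significant — requires the true p
#' to be at least .05). The perturbed result is re-rendered through the
#' checker to confirm the intended classification; if no perturbation
#' achieves it (the true p leaves no room) an error of class
#' `"reportcheck_resample"` is thrown so callers can resample the
#' underlying result.
#'
#' @param result One-row results data frame (a true, consistent result).
#' @param class `"small"`, `"large"`, or `"gross"`.
#' @param true_p The exact p value behind the printed statistic.
#' @param tries Number of candidate perturbations to attempt.
#' @return The one-row results data frame with `p_comparator = "eq"` and
#'   a perturbed `p_text`.
#' @export
inject_error <- function(result, class = c("small", "large", "gross"),
                         true_p, tries = 60) {
  class <- match.arg(class)
  stopifnot(is.data.frame(result), nrow(result) == 1L)
  if (class == "gross" && true_p < 0.05)
    stop(structure(class = c("reportcheck_resample", "error", "condition"),
                   list(message = "gross error needs a non-significant truth",
                        call = sys.call())))
  for (i in seq_len(tries)) {
    cand <- switch(class,
      small = true_p + sample(c(-1, 1), 1) *
        stats::runif(1, 0.002, 0.0093),
      large = {
        delta <- stats::runif(1, 0.012, 0.03)
        if (true_p + delta < 0.0492) true_p + delta else true_p - delta
      },
      gross = stats::runif(1, 0.002, 0.045)
    )
    if (cand < 0.0015 || cand > 0.0494) next
    out <- result
    out$p_comparator <- "eq"
    out$p_text <- format_p_text(cand, 3)
    v <- verdict_of(out)
    # large and gross are nested within error, and a gross error is
    # typically also large; the injected classes are therefore
    # small = error only, large = large but not gross, gross = gross
    ok <- switch(class,
      small = v$error_class == "error" && !v$is_large && !v$is_gross,
      large = v$is_large && !v$is_gross,
      gross = v$is_gross)
    if (ok && include_result(out)) return(out)
  }
  stop(structure(class = c("reportcheck_resample", "error", "condition"),
                 list(message = sprintf(
                   "no %s perturbation achievable at true p %.4f",
                   class, true_p), call = sys.call())))
}

# draw one raw (clean) result for a study; returns row + true values
draw_true_result <- function(spec, article_id, study, n_study, family,
                             deficit, effect_scale, null_effect = FALSE) {
  repeat {
    d <- if (null_effect) 0 else
      stats::rlnorm(1, spec$effect_meanlog, spec$effect_sdlog) * effect_scale
    if (family == "t") {
      df1 <- NA_real_
      df2 <- n_study - 2 - deficit
      stat <- stats::rt(1, df2, ncp = d * sqrt(n_study / 4)) *
        sample(c(-1, 1), 1)
    } else {
      df1 <- sample(1:3, 1)
      df2 <- n_study - df1 - 1 - deficit
      stat <- stats::rf(1, df1, df2, ncp = d^2 * n_study / 4)
    }
    if (df2 < 3)
      stop("study sample size too small for the requested design")
    true_p <- recompute_p(family, df1, df2, stat)
    keep <- if (null_effect) true_p >= 0.055 else
      (!spec$sig_filter || true_p < 0.05)
    if (!keep) next
    row <- one_result_row(article_id, study, family, df1, df2,
                          format_stat_text(stat), "eq",
                          format_p_text(max(true_p, 1e-4), 3))
    return(list(row = row, true_stat = stat, true_p = true_p))
  }
}

# choose the printed form of a clean (consistent) result; printed forms
# are kept strictly below .05 so the inclusion filter retains them
report_clean <- function(row, true_p) {
  style <- sample(c("eq3", "eq2", "lt05", "lt001"), 1,
                  prob = c(0.6, 0.15, 0.15, 0.1))
  if (true_p >= 0.0485) style <- "lt05"
  if (style == "lt001" && true_p >= 0.001) style <- "eq3"
  if (style == "eq2" &&
      (round(true_p, 2) < 0.005 || round(true_p, 2) > 0.0449)) style <- "eq3"
  if (style == "eq3" && round(true_p, 3) < 0.0005) style <- "lt001"
  switch(style,
    eq3 = { row$p_comparator <- "eq"; row$p_text <- format_p_text(true_p, 3) },
    eq2 = { row$p_comparator <- "eq"; row$p_text <- format_p_text(true_p, 2) },
    lt05 = { row$p_comparator <- "lt"; row$p_text <- ".05" },
    lt001 = { row$p_comparator <- "lt"; row$p_text <- ".001" }
  )
  row
}

sentence_templates <- c(
  "In Study %STUDY%, the manipulation produced a reliable difference, %RES%.",
  "As predicted, the effect was significant, %RES%, replicating earlier work.",
  "The interaction reached significance, %RES%, so the groups were analysed separately.",
  "Participants in the treatment condition scored higher, %RES%.",
  "This difference was reliable, %RES%, consistent with our hypothesis.",
  "An analysis of variance confirmed the effect, %RES%.",
  "Follow-up contrasts supported the prediction, %RES%."
)

filler_sentences <- c(
  "Participants completed the task in a quiet room.",
  "All materials were counterbalanced across conditions.",
  "Responses were recorded with standard equipment.",
  "The procedure followed the protocol of the earlier studies.",
  "Descriptive statistics are reported in the supplementary tables."
)

render_article_text <- function(article_id, journal, studies, rendered) {
  intro <- sprintf(
    "Article %s, published in %s, reports %d stud%s (%s).",
    article_id, journal, nrow(studies),
    if (nrow(studies) == 1) "y" else "ies",
    paste(sprintf("Study %d with N = %d", studies$study, studies$n_total),
          collapse = "; "))
  body <- vapply(seq_along(rendered), function(i) {
    tmpl <- sample(sentence_templates, 1)
    s <- sub("%RES%", rendered[i], sub("%STUDY%", "1", tmpl, fixed = TRUE),
             fixed = TRUE)
    if (stats::runif(1) < 0.3) s <- paste(s, sample(filler_sentences, 1))
    s
  }, character(1))
  paste(c(intro, body), collapse = " ")
}

#' Generate a synthetic article corpus with ground truth
#'
#' Produces rendered article text, the accompanying metadata table, and a
#' ground-truth record of every generated result and injection, so that
#' the whole pipeline — scanning, consistency checking, df screening,
#' article summaries, group comparisons — can be validated against known
#' answers. True p values arise mechanistically: an effect size and a
#' sample size are drawn, a noncentral t or F statistic is simulated, and
#' the p value follows from the statistic, which preserves the
#' statistic/df/p coherence the checker relies on and yields the
#' right-skewed distribution of significant p values seen in real
#' corpora. Articles selected for undisclosed exclusions have all their
#' test dfs reduced by the deficit while the metadata keeps the described
#' sample size — exactly the signature the df screen looks for.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (overrides `spec$seed`).
#' @return List with `documents` (article_id, text, group, journal),
#'   `metadata` (per-article description: sample sizes, designs,
#'   reported exclusions/missing), and `ground_truth` (list of `results`
#'   and `articles` data frames).
#' @export
generate_corpus <- function(spec = synthetic_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  docs <- list(); meta <- list(); gt_res <- list(); gt_art <- list()
  idx <- 0L
  for (g in names(spec$n_articles)) {
    for (a in seq_len(spec$n_articles[[g]])) {
      idx <- idx + 1L
      id <- sprintf("a%03d", idx)
      journal <- sample(spec$journals, 1)
      n_studies <- sample.int(spec$n_studies_max, 1)
      # study sizes pairwise further apart than any deficit, so an
      # injected deficit can never coincide with another study's df
      repeat {
        ns <- pmax(spec$n_min,
                   round(stats::rlnorm(n_studies, spec$n_meanlog,
                                       spec$n_sdlog)))
        if (n_studies == 1 ||
            min(dist(ns)) > spec$deficit_max + 1) break
      }
      studies <- data.frame(study = seq_len(n_studies),
                            design = "independent_two_sample",
                            n_total = ns, exclusions = 0, missing = 0)
      deficit <- if (stats::runif(1) < spec$exclusion_rate)
        sample.int(spec$deficit_max, 1) else 0L
      m <- rztnb(1, spec$results_mean[[g]], spec$results_dispersion)
      rates <- spec$error_rates * spec$error_mult[[g]]
      classes <- sample(c("none", "small", "large", "gross"), m,
                        replace = TRUE,
                        prob = c(1 - sum(rates) - spec$one_tailed_rate,
                                 rates))
      one_tailed <- classes == "none" &
        stats::runif(m) < (if (sum(classes == "none")) spec$one_tailed_rate /
                             max(mean(classes == "none"), 1e-9) else 0)
      rows <- vector("list", m); rendered <- character(m)
      for (r in seq_len(m)) {
        family <- if (r == 1L) "t" else
          if (stats::runif(1) < spec$prop_t) "t" else "F"
        study <- sample.int(n_studies, 1)
        repeat {
          tr <- draw_true_result(spec, id, study, ns[study], family,
                                 deficit, spec$effect_scale[[g]],
                                 null_effect = classes[r] == "gross")
          row <- tr$row
          done <- tryCatch({
            if (classes[r] == "none") {
              if (one_tailed[r] && family == "t" &&
                  tr$true_p / 2 >= 0.0005) {
                row$p_comparator <- "eq"
                row$p_text <- format_p_text(tr$true_p / 2, 3)
              } else {
                one_tailed[r] <- FALSE
                row <- report_clean(row, tr$true_p)
              }
            } else {
              row <- inject_error(row[, setdiff(names(row), "study")],
                                  classes[r], tr$true_p)
              row$study <- study
            }
            TRUE
          }, reportcheck_resample = function(e) FALSE)
          if (done) break
        }
        style <- sample(c("canonical", "italics", "tight"), 1)
        txt <- render_result(row[, setdiff(names(row), "study")], style)
        if (grepl("^-", row$statistic_text) && stats::runif(1) < 0.3)
          txt <- sub("-", "−", txt, fixed = TRUE)
        if (one_tailed[r]) txt <- paste0(txt, ", one-tailed")
        rendered[r] <- txt
        row$true_statistic <- tr$true_stat
        row$true_p <- tr$true_p
        row$injected_class <- classes[r]
        row$one_tailed <- one_tailed[r]
        rows[[r]] <- row
      }
      docs[[idx]] <- data.frame(
        article_id = id,
        text = render_article_text(id, journal, studies, rendered),
        group = g, journal = journal, stringsAsFactors = FALSE)
      meta[[idx]] <- data.frame(
        article_id = id, group = g, journal = journal,
        sample_sizes = paste(ns, collapse = ";"),
        designs = paste(studies$design, collapse = ";"),
        exclusions = paste(studies$exclusions, collapse = ";"),
        missing = paste(studies$missing, collapse = ";"),
        stringsAsFactors = FALSE)
      gt_res[[idx]] <- do.call(rbind, rows)
      gt_art[[idx]] <- data.frame(
        article_id = id, group = g, journal = journal,
        df_deficit = deficit, n_results = m, stringsAsFactors = FALSE)
    }
  }
  list(documents = do.call(rbind, docs),
       metadata = do.call(rbind, meta),
       ground_truth = list(results = do.call(rbind, gt_res),
                           articles = do.call(rbind, gt_art)))
}
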