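#' Wilcoxon rank-sum comparison of two article groups
#'
#' Reports the rank-sum statistic W of the first sample (sum of its
#' midranks in the pooled ordering) together with the p value of the
#' two-sample Wilcoxon test. Small samples are tested by exact
#' enumeration (untied ones via [stats::wilcox.test()], tied ones by
#' enumerating the permutation distribution of the midrank sum); larger
#' samples use the normal approximation with tie correction.
#'
#' @param x,y Numeric vectors (article-level measures per group).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `W` (rank sum of `x`), `U` (Mann-Whitney statistic,
#'   `W` minus its minimum), `p` and `alternative`. `W` always lies in
#'   `[n1(n1+1)/2, n1 n2 + n1(n1+1)/2]`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n <- n1 + length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)])
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (all(c(x, y) == c(x, y)[1])) {
    p <- 1
  } else if (has_ties && choose(n, n1) <= 10000) {
    # tied small samples: wilcox.test cannot be exact, so enumerate the
    # permutation distribution of the midrank sum directly
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(rk[combos], nrow = n1))
    e_w <- n1 * (n + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(w_all - e_w) >= abs(W - e_w) - 1e-9),
      greater = mean(w_all >= W - 1e-9),
      less = mean(w_all <= W + 1e-9))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative)$p.value)
  }
  list(W = W, U = W - n1 * (n1 + 1) / 2, p = p, alternative = alternative)
}

#' Empirical null of W by group-label reassignment
#'
#' Randomly reassigns the articles (each carrying its article-level
#' value) to the two groups, preserving the group sizes, and collects the
#' rank-sum statistic W of the first group to form an empirical null
#' distribution for the observed W. The empirical p uses the add-one
#' correction `(1 + #extreme) / (reps + 1)`, so it is never exactly zero.
#' With `method = "exhaustive"` all distinct assignments are enumerated
#' (feasible for small corpora) and the exact permutation p
#' `#extreme / #assignments` is returned.
#'
#' @param values Per-article values (e.g. median recomputed p).
#' @param n1,n2 Group sizes; `n1 + n2` must equal `length(values)` and
#'   the observed grouping is taken to be the first `n1` values vs the
#'   rest.
#' @param reps Number of reassignments (ignored for exhaustive).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (extremeness as `|W - E[W]|`),
#'   `"greater"`, or `"less"` (signed comparisons).
#' @param method `"sample"` or `"exhaustive"`.
#' @return List with `observed_W`, `reps`, `p_empirical`, `seed`,
#'   `alternative`, `method`.
#' @export
permutation_null_w <- function(values, n1, n2, reps = 100000L, seed = NULL,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               method = c("sample", "exhaustive")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  if (n1 + n2 != length(values)) stop("n1 + n2 must equal length(values)")
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  rk <- rank(values)
  w_obs <- sum(rk[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  extremeness <- switch(alternative,
    two.sided = function(w) abs(w - e_w) >= abs(w_obs - e_w) - 1e-9,
    greater = function(w) w >= w_obs - 1e-9,
    less = function(w) w <= w_obs + 1e-9
  )
  if (method == "exhaustive") {
    combos <- utils::combn(n, n1)
    w_null <- colSums(matrix(rk[combos], nrow = n1))
    p <- mean(extremeness(w_null))
    reps <- ncol(combos)
  } else {
    w_null <- vapply(seq_len(reps),
                     function(i) sum(rk[sample.int(n, n1)]), numeric(1))
    p <- (1 + sum(extremeness(w_null))) / (reps + 1)
  }
  list(observed_W = w_obs, reps = reps, p_empirical = p,
       seed = if (is.null(seed)) NA_integer_ else seed,
       alternative = alternative, method = method)
}

#' Negative binomial regression of error counts
#'
#' Fits `count ~ group + log(n_stats)` with a log link and
#' maximum-likelihood dispersion ([MASS::glm.nb()]): articles that report
#' more statistics have more opportunity for errors, so the number of
#' reported statistics enters as a (log) covariate rather than an offset,
#' and the group coefficient measures the error-count difference between
#' article groups at equal output. When the dispersion estimate diverges
#' (counts effectively Poisson) the fit falls back to a Poisson GLM with
#' a warning; when no article has any error the regression is
#' unidentifiable and the Fisher exact test on article-level flags is the
#' appropriate fallback (see [fisher_exact_2x2()]).
#'
#' @param counts Per-article error counts (non-negative integers).
#' @param group Per-article group indicator (0/1 or a two-level factor).
#' @param n_stats Per-article number of reported statistics (>= 1).
#' @return List with `coefficients` (data frame: estimate, se, z, p for
#'   intercept, group, log n_stats), `theta` (NB dispersion; `NA` for the
#'   Poisson fallback), `theta_se`, `model` (`"negative_binomial"` or
#'   `"poisson"`), and `fit` (the underlying glm object).
#' @export
nb_regression <- function(counts, group, n_stats) {
  stopifnot(length(counts) == length(group),
            length(counts) == length(n_stats))
  if (length(counts) < 10)
    stop("need at least 10 articles for a count regression")
  if (any(n_stats < 1)) stop("n_stats must be >= 1")
  if (all(counts == 0))
    stop("all counts are zero; use fisher_exact_2x2() on article flags")
  group <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  dat <- data.frame(counts = counts, group = group,
                    log_n = log(as.numeric(n_stats)))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ group + log_n, data = dat)),
    error = function(e) NULL)
  model <- "negative_binomial"
  if (is.null(fit) || !fit$converged || fit$theta > 1e5) {
    warning("negative binomial dispersion diverged; falling back to Poisson")
    fit <- stats::glm(counts ~ group + log_n, data = dat, family = "poisson")
    model <- "poisson"
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = c("intercept", "group", "log_n_stats"),
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
    row.names = NULL
  )
  list(coefficients = coefs,
       theta = if (model == "negative_binomial") fit$theta else NA_real_,
       theta_se = if (model == "negative_binomial") fit$SE.theta else
         NA_real_,
       model = model, fit = fit)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p value obtained by summing the probabilities of all tables
#' (with the observed margins) no more probable than the observed one
#' under the hypergeometric null. A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows: groups;
#'   columns: e.g. articles with / without at least one error).
#' @return The two-sided p value.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Monte Carlo power of the two-sample Wilcoxon test
#'
#' Draws two samples of `n_per_group` values from unit-variance normal
#' distributions whose means differ by the standardized effect `d`,
#' applies the two-sided Wilcoxon rank-sum test, and reports the fraction
#' of replications rejecting at level `alpha`.
#'
#' @param d Standardized mean difference.
#' @param n_per_group Sample size per group.
#' @param alpha Significance level in (0, 1).
#' @param reps Number of replications (>= 1000 for a stable estimate).
#' @param seed Optional integer seed.
#' @return List with `power`, `d`, `n_per_group`, `alpha`, `reps`,
#'   `seed`.
#' @examples
#' \donttest{
#' wilcoxon_power_sim(d = 0.5, n_per_group = 90, reps = 2000, seed = 1)
#' }
#' @export
wilcoxon_power_sim <- function(d, n_per_group, alpha = 0.05, reps = 10000L,
                               seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, reps >= 1, n_per_group >= 2)
  if (!is.null(seed)) set.seed(seed)
  reject <- logical(reps)
  for (i in seq_len(reps)) {
    x <- stats::rnorm(n_per_group)
    y <- stats::rnorm(n_per_group, mean = d)
    reject[i] <- stats::wilcox.test(x, y)$p.value < alpha
  }
  list(power = mean(reject), d = d, n_per_group = n_per_group,
       alpha = alpha, reps = reps,
       seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Run the full article-group comparison suite
#'
#' Given article-level records, compares the two groups on the median
#' recomputed p value with the Wilcoxon rank-sum test (overall and per
#' journal) and the label-reassignment permutation null, regresses the
#' error counts (any, large, gross) on group and log number of
#' statistics with negative binomial models, and computes Fisher exact
#' tests on the article-level error flags.
#'
#' @param articles Article-level data frame from [summarize_articles()];
#'   `group` must have exactly two levels. The first level in sorted
#'   order is taken as the reference (indicator 0).
#' @param reps Permutation replications (default 100000).
#' @param seed Optional integer seed for the permutation null.
#' @param alternative Sidedness for the Wilcoxon and permutation tests.
#' @return Nested list: `groups`, `wilcoxon` (total and per journal),
#'   `permutation`, `nb` (one entry per error type, or the Fisher
#'   fallback when counts are all zero), `fisher` (one p per error
#'   type).
#' @export
compare_groups <- function(articles, reps = 100000L, seed = NULL,
                           alternative = "two.sided") {
  stopifnot(is.data.frame(articles))
  lev <- sort(unique(articles$group))
  if (length(lev) != 2) stop("articles must contain exactly two groups")
  g1 <- articles[articles$group == lev[2], , drop = FALSE]  # treatment
  g0 <- articles[articles$group == lev[1], , drop = FALSE]  # reference
  wtest <- function(a, b) wilcoxon_rank_sum(a, b, alternative = alternative)
  wil <- list(total = wtest(g1$median_recomputed_p, g0$median_recomputed_p))
  for (j in sort(unique(articles$journal))) {
    a <- g1$median_recomputed_p[g1$journal == j]
    b <- g0$median_recomputed_p[g0$journal == j]
    if (length(a) && length(b)) wil[[j]] <- wtest(a, b)
  }
  perm <- permutation_null_w(
    c(g1$median_recomputed_p, g0$median_recomputed_p),
    n1 = nrow(g1), n2 = nrow(g0), reps = reps, seed = seed,
    alternative = alternative)
  indicator <- as.numeric(c(g1$group, g0$group) == lev[2])
  nb <- list()
  fisher <- list()
  for (type in c("error", "large", "gross")) {
    col <- paste0("n_", type)
    counts <- c(g1[[col]], g0[[col]])
    n_stats <- c(g1$n_significant, g0$n_significant)
    nb[[type]] <- if (all(counts == 0))
      list(model = "fisher_fallback") else
      nb_regression(counts, indicator, n_stats)
    tab <- rbind(c(sum(g1[[col]] > 0), sum(g1[[col]] == 0)),
                 c(sum(g0[[col]] > 0), sum(g0[[col]] == 0)))
    fisher[[type]] <- fisher_exact_2x2(tab)
  }
  list(groups = list(reference = lev[1], treatment = lev[2],
                     n = c(nrow(g0), nrow(g1))),
       wilcoxon = wil, permutation = perm, nb = nb, fisher = fisher)
}
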