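test_that("rank-sum statistic and exact p match brute-force enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(res$W, 3)            # minimal rank sum
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 6)        # one assignment of six is as small
  expect_equal(res$p, oracle_wilcoxon_p(c(1, 2), c(3, 4), "less"))

  set.seed(71)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:5, 1)), 3)
    y <- round(rnorm(sample(3:5, 1)), 3)
    alt <- sample(c("two.sided", "greater", "less"), 1)
    expect_equal(wilcoxon_rank_sum(x, y, alt)$p,
                 oracle_wilcoxon_p(x, y, alt), tolerance = 1e-10,
                 info = paste("rep", i, alt))
  }
})

test_that("degenerate and bounded cases of the rank sum", {
  expect_equal(wilcoxon_rank_sum(rep(1, 4), rep(1, 5))$p, 1)
  set.seed(72)
  for (i in 1:20) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    W <- wilcoxon_rank_sum(rnorm(n1), rnorm(n2))$W
    expect_true(W >= n1 * (n1 + 1) / 2 && W <= n1 * n2 + n1 * (n1 + 1) / 2)
  }
})

test_that("exhaustive permutation null equals exact enumeration", {
  set.seed(73)
  for (i in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- round(rnorm(n1 + n2), 3)
    perm <- permutation_null_w(vals, n1, n2, method = "exhaustive")
    expect_equal(perm$p_empirical,
                 oracle_wilcoxon_p(vals[seq_len(n1)], vals[-seq_len(n1)],
                                   "two.sided"), tolerance = 1e-12)
  }
})

test_that("sampled permutation p is reproducible and calibrated", {
  vals <- c(0.002, 0.004, 0.010, 0.003, 0.008, 0.001, 0.005, 0.020)
  a <- permutation_null_w(vals, 4, 4, reps = 500, seed = 9)
  b <- permutation_null_w(vals, 4, 4, reps = 500, seed = 9)
  expect_equal(a$p_empirical, b$p_empirical)
  expect_true(a$p_empirical >= 1 / 501 && a$p_empirical <= 1)
  expect_error(permutation_null_w(vals, 0, 8), "non-empty")
  expect_error(permutation_null_w(vals, 3, 4), "length")
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 3, 0), 2, byrow = TRUE)), 1)
  set.seed(74)
  for (i in 1:30) {
    tab <- matrix(rpois(4, sample(3:12, 1)), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("negative binomial regression recovers known coefficients", {
  set.seed(75)
  n <- 300
  group <- rep(0:1, each = n / 2)
  n_stats <- pmax(1, rnbinom(n, mu = 15, size = 2))
  b0 <- -2.3; b1 <- 0.5; b2 <- 1
  mu <- exp(b0 + b1 * group + b2 * log(n_stats))
  counts <- rnbinom(n, mu = mu, size = 0.8)
  fit <- nb_regression(counts, group, n_stats)
  est <- fit$coefficients
  expect_equal(fit$model, "negative_binomial")
  expect_true(abs(est$estimate[est$term == "group"] - b1) <
                2 * est$se[est$term == "group"])
  expect_true(abs(est$estimate[est$term == "log_n_stats"] - b2) <
                2 * est$se[est$term == "log_n_stats"])
  expect_true(fit$theta > 0)
})

test_that("no-signal counts give null coefficients (Poisson fallback)", {
  n_stats <- rep(c(5, 10, 20), 10)
  counts <- rep(2L, 30)
  group <- rep(0:1, 15)
  expect_warning(fit <- nb_regression(counts, group, n_stats), "Poisson")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "group"], 0, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "log_n_stats"], 0, tolerance = 1e-6)
  expect_error(nb_regression(rep(0L, 30), group, n_stats), "fisher")
})

test_that("power simulation hits the trivial calibration points", {
  null_power <- wilcoxon_power_sim(d = 0, n_per_group = 40, reps = 1500,
                                   seed = 76)$power
  expect_true(abs(null_power - 0.05) < 0.02)
  sat <- wilcoxon_power_sim(d = 3, n_per_group = 40, reps = 200,
                            seed = 77)$power
  expect_equal(sat, 1)
})

test_that("the comparison suite runs end to end on a synthetic corpus", {
  corpus <- generate_corpus(synthetic_spec(
    n_articles = c(outliers_removed = 12, no_removal = 10)), seed = 78)
  out <- analyze_corpus(corpus$documents, corpus$metadata)
  cmp <- compare_groups(out$articles, reps = 400, seed = 79)
  expect_equal(cmp$groups$treatment, "outliers_removed")
  expect_true(cmp$wilcoxon$total$p >= 0 && cmp$wilcoxon$total$p <= 1)
  expect_true(cmp$permutation$p_empirical > 0)
  expect_equal(cmp$permutation$reps, 400)
  expect_named(cmp$nb, c("error", "large", "gross"))
  expect_named(cmp$fisher, c("error", "large", "gross"))
  for (p in unlist(cmp$fisher)) expect_true(p >= 0 && p <= 1)
})
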