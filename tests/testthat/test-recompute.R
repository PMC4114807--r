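test_that("p recomputation matches the distribution tails", {
  expect_equal(round(recompute_p("F", 1, 23, 4.45), 3), 0.046)
  expect_equal(recompute_p("t", NA, 23, 0), 1)
  # two-tailed t(v) equals F(1, v) at the squared statistic
  set.seed(11)
  for (i in 1:50) {
    df2 <- sample(3:150, 1)
    s <- runif(1, 0, 5)
    expect_equal(recompute_p("t", NA, df2, s),
                 recompute_p("F", 1, df2, s^2), tolerance = 1e-10)
  }
  # strictly decreasing in |statistic|
  s <- seq(0, 6, by = 0.25)
  expect_true(all(diff(recompute_p("t", NA, 30, s)) < 0))
  expect_true(all(diff(recompute_p("F", 2, 30, s[-1])) < 0))
  expect_error(recompute_p("t", NA, 30, Inf), "finite")
  expect_error(recompute_p("F", 1, 30, -1), "non-negative")
})

test_that("rounding intervals honour printed precision", {
  iv <- rounding_interval("4.45")
  expect_equal(c(iv$lo, iv$hi), c(4.445, 4.455))
  expect_true(iv$lo_closed)
  expect_false(iv$hi_closed)
  iv <- rounding_interval("4.450")
  expect_equal(c(iv$lo, iv$hi), c(4.4495, 4.4505))
  iv <- rounding_interval("2")
  expect_equal(c(iv$lo, iv$hi), c(1.5, 2.5))
  expect_error(rounding_interval("abc"), "not a finite")
})

test_that("reported p claims map to the right intervals", {
  iv <- reported_p_interval("eq", ".046")
  expect_equal(c(iv$lo, iv$hi), c(0.0455, 0.0465))
  iv <- reported_p_interval("lt", ".001")
  expect_equal(c(iv$lo, iv$hi), c(0, 0.001))
  expect_false(iv$lo_closed)
  expect_false(iv$hi_closed)
  iv <- reported_p_interval("gt", ".05")
  expect_equal(c(iv$lo, iv$hi), c(0.05, 1))
  expect_true(iv$hi_closed)
  expect_error(reported_p_interval("eq", "1.2"), "out of range")
})

test_that("worked example and frozen verdicts", {
  v <- check_consistency(scan_text("F(1,23) = 4.45, p = .046"))
  expect_true(v$consistent)
  expect_equal(v$error_class, "none")

  # recomputed two-tailed p for t(20) = 1.50 is 0.1492 (frozen from the
  # t CDF): reported .04 is an error, large (off by > .01) and gross
  # (reported significant, recomputed non-significant)
  v <- check_consistency(scan_text("t(20) = 1.50, p = .04"))
  expect_equal(v$p_recomputed, 0.1492358, tolerance = 1e-6)
  expect_false(v$consistent)
  expect_true(v$is_large)
  expect_true(v$is_gross)

  # interval lower edge dips below .05, so 'p < .05' is defensible
  v <- check_consistency(scan_text("t(23) = 2.11, p < .05"))
  expect_true(v$consistent)
})

test_that("error classification partitions and nests correctly", {
  out <- classify_error(0.018, reported_p_interval("eq", ".013"),
                        consistent = FALSE, p_reported_point = 0.013)
  expect_equal(out$error_class, "error")
  expect_false(out$is_large)   # |.013 - .018| = .005 <= .01
  expect_false(out$is_gross)   # still significant after recomputation
  out <- classify_error(0.149, reported_p_interval("eq", ".04"),
                        consistent = FALSE, p_reported_point = 0.04)
  expect_true(out$is_large)
  expect_true(out$is_gross)
  out <- classify_error(0.149, reported_p_interval("eq", ".04"),
                        consistent = TRUE, p_reported_point = 0.04)
  expect_equal(out, list(error_class = "none", is_large = FALSE,
                         is_gross = FALSE))
})

test_that("the point recomputation always lies inside the propagated interval", {
  set.seed(21)
  rs <- random_results(200)
  v <- check_consistency(rs)
  for (i in seq_len(nrow(rs))) {
    iv <- reportcheck:::statistic_p_interval(rs$test_family[i], rs$df1[i],
                                             rs$df2[i], rs$statistic_text[i])
    expect_true(v$p_recomputed[i] >= iv$lo - 1e-12 &&
                  v$p_recomputed[i] <= iv$hi + 1e-12)
  }
  # flags only occur inside the error class
  expect_true(all(!v$is_large | v$error_class == "error"))
  expect_true(all(!v$is_gross | v$error_class == "error"))
  expect_true(all(v$error_class[v$consistent] == "none"))
})

test_that("interval verdicts agree with the grid-search oracle", {
  set.seed(31)
  rs <- random_results(400)
  v <- check_consistency(rs)
  oracle <- vapply(seq_len(nrow(rs)), function(i)
    oracle_consistent(rs$test_family[i], rs$df1[i], rs$df2[i],
                      rs$statistic_text[i], rs$p_comparator[i],
                      rs$p_text[i]), logical(1))
  expect_equal(v$consistent, oracle)
})

test_that("one-tailed salvage is applied only in context, and can be disabled", {
  txt <- "As a one-tailed test predicted, t(28) = 1.90, p = .034."
  r <- scan_text(txt)
  expect_equal(r$tail_note, "one_tailed_context")
  v <- check_consistency(r)
  expect_true(v$consistent)       # halved interval covers .034
  expect_true(v$one_tailed_salvage)
  strict <- check_consistency(r, one_tailed_salvage = FALSE)
  expect_false(strict$consistent)
  # same numbers without the context cue stay an error
  v2 <- check_consistency(scan_text("We found t(28) = 1.90, p = .034."))
  expect_false(v2$consistent)
  expect_false(v2$one_tailed_salvage)
})
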