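# Independent oracles used to cross-check the implementation.
# These deliberately avoid the package's own interval logic.

# Grid-search consistency oracle: sample statistic values across the
# printed statistic's rounding interval and ask whether any achievable
# p value satisfies the reported claim (rounds to the printed p, or
# falls below/above the printed bound).
oracle_consistent <- function(family, df1, df2, statistic_text,
                              p_comparator, p_text, grid = 1000) {
  k <- nchar(sub("^[^.]*\\.?", "", statistic_text))
  v <- as.numeric(statistic_text)
  u <- 10^(-k)
  s <- seq(v - u / 2, v + u / 2 - u * 1e-9, length.out = grid)
  p <- if (family == "t") 2 * pt(-abs(s), df2) else {
    s <- pmax(s, 0)
    pf(s, df1, df2, lower.tail = FALSE)
  }
  pv <- as.numeric(p_text)
  kp <- nchar(sub("^[^.]*\\.?", "", p_text))
  up <- 10^(-kp)
  switch(p_comparator,
    eq = any(p >= pv - up / 2 & p < pv + up / 2),
    lt = any(p < pv),
    gt = any(p > pv)
  )
}

# Exhaustive two-sided Fisher p by enumerating all tables with the
# observed margins and summing hypergeometric probabilities no larger
# than the observed table's.
oracle_fisher <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (m1 == 0 || m2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - m2):min(c1, m1)
  probs <- dhyper(xs, m1, m2, c1)
  obs <- dhyper(tab[1, 1], m1, m2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force exact rank-sum distribution over all assignments.
oracle_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  combos <- combn(n, n1)
  w_all <- colSums(matrix(rk[combos], nrow = n1))
  e_w <- n1 * (n + 1) / 2
  switch(alternative,
    two.sided = mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9),
    greater = mean(w_all >= w_obs - 1e-9),
    less = mean(w_all <= w_obs + 1e-9)
  )
}

# Random well-formed reported results for property tests.
random_results <- function(n) {
  family <- sample(c("t", "F"), n, replace = TRUE)
  df1 <- ifelse(family == "F", sample(1:4, n, replace = TRUE), NA_real_)
  df2 <- sample(5:200, n, replace = TRUE)
  stat <- ifelse(family == "t",
                 round(rt(n, df2) + rnorm(n, 0, 2), 2),
                 round(rf(n, ifelse(is.na(df1), 1, df1), df2) +
                         abs(rnorm(n, 0, 2)), 2))
  stat <- ifelse(family == "F", abs(stat), stat)
  comparator <- sample(c("eq", "lt", "gt"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
  p_raw <- round(runif(n, 0.0005, 0.9), sample(2:3, n, replace = TRUE))
  p_raw[comparator == "lt"] <- sample(c(0.05, 0.01, 0.001),
                                      sum(comparator == "lt"),
                                      replace = TRUE)
  p_raw[comparator == "gt"] <- 0.05
  p_raw[p_raw <= 0] <- 0.001
  data.frame(
    article_id = NA_character_, test_family = family, df1 = df1, df2 = df2,
    statistic_text = sprintf("%.2f", stat),
    p_comparator = comparator,
    p_text = sub("^0", "", format(p_raw, trim = TRUE, scientific = FALSE)),
    span_start = NA_integer_, span_end = NA_integer_,
    source = "auto", tail_note = "none", stringsAsFactors = FALSE
  )
}
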