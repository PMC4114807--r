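---
title: "Methods: rounding-aware consistency checking and article-level inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rounding-aware consistency checking and article-level inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportcheck)
```

## The problem

Null-hypothesis significance tests are reported as a triplet — test
statistic, degrees of freedom, p value — and the triplet is redundant: the
p value is a deterministic function of the other two. That redundancy
makes published results auditable. A *reporting error* is a printed p
value that cannot be reconciled with the printed statistic and df; a
*gross* error is one that overturns the claimed significance. At the
article level, error counts and the distribution of (recomputed)
significant p values are usable indicators of analytic care, and can be
compared between groups of articles defined by some practice of interest —
here, whether or not the article reported removing outliers before
analysis.

This vignette records the package's modelling choices, the rationale for
each, and what the validation on synthetic corpora does and does not
establish.

## Extraction

`scan_text()` recognises completely reported APA-style t and F results:
statistic, dfs, and p value, with optional italics markers, flexible
spacing, en-dash or Unicode minus, an optional leading zero in the p
value, Welch-style fractional dfs, and a bare `ns` (captured as
`p > .05`). Incomplete fragments are never guessed at: a result missing
any element of the triplet is skipped, because the consistency check is
meaningless without all three. Printed precision is preserved as text —
`"4.450"` is a sharper claim than `"4.45"` and the checker needs the
distinction.

Results written in non-standard layouts (typically with an effect size
interposed between statistic and p value) are out of reach of a reliable
regular expression; chasing them with unbounded gap matching produces
false captures. They enter instead through `read_manual_results()`, a
validated hand-entry table, mirroring how a human coder would handle them.
Chi-square, r and z statistics are out of scope by design. Decimal commas
are not supported; input is assumed to be period-decimal English text.

A configurable window (default 100 characters each side) around each match
is searched for "one-tailed"/"one-sided", because a one-sided test
reported at half the two-tailed p would otherwise masquerade as an error.

## The consistency rule

Both printed numbers stand for rounding intervals: a value printed with
$k$ decimals stands for $[v - u/2,\, v + u/2)$ with $u = 10^{-k}$
(trailing zeros count toward $k$; the half-open convention is immaterial
at the measurement scale of the problem but is applied uniformly). The
statistic's interval is pushed through the p mapping — strictly decreasing
in $|s|$ for both the t and F families, so the image is again an interval,
with endpoint closures carried along; an interval straddling zero for a t
statistic attains $p = 1$ at its interior. The reported p admits an
interval by comparator: `eq` its rounding interval (clipped to the unit
interval), `lt` the open interval $(0, \pi)$, `gt` $(\pi, 1]$.

The result is **consistent** when the two intervals share at least one
point. Interval overlap is the most permissive defensible rule — it flags
a result only when *no* value the author could honestly have computed
rounds to what was printed — which minimises false accusations at the cost
of missing some true errors. The alternative (comparing point
recomputation against the reported interval only) flags results whose
statistic rounding alone explains the discrepancy; we verified on random
results that the difference is confined to boundary cases. A grid-search
oracle (1,000 statistic values across the rounding interval, tested
against the reported claim) reproduces the interval verdicts exactly on
10,000 random results in the acceptance suite.

Error magnitude uses point values, not intervals: `is_large` requires
$|\pi - p^*| > .01$ where $\pi$ is the printed value (the bound for
`lt`/`gt`) and $p^*$ the recomputation from the printed statistic —
"differences in p" is a point notion. `is_gross` requires the reported
interval to lie entirely below .05 while $p^* \ge .05$. Large and gross
are nested within error and may co-occur: a gross error's reported and
recomputed p straddle .05 and almost always differ by more than .01. A
printed `p = .05` is *not* treated as significant — its rounding interval
straddles the threshold — and `p < .05` is.

Inconsistent results in a one-tailed context are salvaged when halving the
recomputed interval restores overlap; salvaged results count as consistent
but carry a flag, and a strict mode (`one_tailed_salvage = FALSE`)
disables the rule. Welch-style fractional dfs are used in the CDF exactly
as printed.

## The df screen

For an independent two-sample t test, df $= N - 2$; paired or one-sample,
$N - 1$, with $N$ the described sample size net of *reported* exclusions
and missingness. Only undisclosed removals should therefore surface as a
df/sample-size discrepancy. The screen is deliberately conservative:
fractional (Welch) dfs and unknown designs yield `indeterminate`, never
`discrepancy`; integer dfs must mismatch *every* described study of the
article (when results cannot be pinned to a study) before the article is
flagged. Design labels come from the metadata table, not text mining —
design classification from prose is a human judgement task with imperfect
inter-rater agreement, and a regex would do worse. The tolerance is zero:
any integer mismatch is a candidate, as the screen's purpose is to bound
how contaminated a "no exclusions reported" control group may be. The
screen cannot distinguish undisclosed exclusion from unreported missing
data or a misprinted df, and is restricted to t tests, where the
df–sample-size relation is unambiguous.

## Article-level reduction and inference

Only results *reported as significant* (reported interval entirely below
.05) enter the article-level measures: the number of significant results,
the median of their recomputed p values (the point recomputation is used
throughout, including when only a `<` bound was printed), error counts,
and the median of the described per-study sample sizes. Medians use the
standard midpoint convention for even counts. Articles with no significant
result are dropped, with a log message — they would not have entered the
sampling frame.

Articles are the unit of analysis because results within an article are
dependent in intractable ways. The comparison suite:

* **Wilcoxon rank-sum** on article medians. W is reported as the rank sum
  of the first group (so $W \in [n_1(n_1+1)/2,\; n_1 n_2 + n_1(n_1+1)/2]$).
  Small untied samples use the exact distribution; small tied samples are
  enumerated exhaustively over assignments (the standard exact algorithm
  does not admit ties); larger samples use the normal approximation with
  tie correction. Default two-sided, with one-sided options exposed — the
  hypotheses motivating such audits are directional, but two-sided tests
  are the safer default.
* **Permutation null of W**: articles are reassigned to the two groups at
  random, preserving group sizes and without journal stratification
  (matching the plain reassignment description this procedure follows);
  the empirical p uses the add-one correction $(1 + \#\text{extreme}) /
  (\text{reps} + 1)$, standard for Monte Carlo tests, so it is never
  exactly zero. Two-sided extremeness is $|W - E[W]|$. An exhaustive mode
  enumerates all assignments for small corpora and then returns the exact
  permutation p without the correction.
* **Negative binomial regression** of per-article error counts on the
  group indicator and log(number of statistics), log link, dispersion by
  maximum likelihood. The covariate enters freely rather than as an
  offset, letting the data determine how error counts scale with output.
  If the dispersion estimate diverges the fit falls back to Poisson with
  a warning; if no article has any error the regression is unidentifiable
  and the Fisher exact test on article-level flags is the designated
  fallback.
* **Fisher exact tests** on 2×2 tables of articles with/without at least
  one error (any, large, gross), two-sided by the standard
  minimum-likelihood rule; a zero margin returns p = 1.
* **Power simulation**: two unit-variance normal samples separated by a
  standardized shift $d$, two-sided rank-sum test, rejection fraction
  across replicates. At $d = 0.5$ and 90 articles per group the simulated
  power is .90 at $\alpha = .05$.

Every stochastic routine takes a single integer seed and records it in
its output.

## The synthetic corpus

`generate_corpus()` exists so the whole pipeline can be validated without
any external data. Its defaults are fixed to the corpus structure the
analysis is designed for: groups of 92 and 61 articles; per-article
significant-result counts from a zero-truncated negative binomial with
means 19.4 and 14.5 and dispersion 1.4, which puts the realized medians
within 2 of 14 and 12 (the dispersion value was chosen once, by computing
truncated-NB medians over a small grid); per-study sample sizes log-normal
with median 82; per-result effect sizes log-normal with median 0.55.

True p values arise mechanistically — draw an effect size and sample
size, simulate a noncentral t or F statistic, compute p — rather than by
sampling p directly. This preserves the statistic/df/p coherence the
checker relies on and produces the right-skewed distribution of
significant p values seen in real corpora (most mass below .01). The
significance filter applies to the truth, mirroring the inclusion rule.

Injections, all verified through the checker at generation time so ground
truth and verdict cannot drift apart:

* **small** errors (default rate .04): the reported p is perturbed beyond
  its rounding tolerance but within .01 of the truth;
* **large** errors (.01): perturbed by more than .01, still significant;
* **gross** errors (.012): the underlying statistic is redrawn under the
  null conditioned on $p \ge .055$ (the margin keeps statistic rounding
  from straddling .05) and a significant p is printed;
* **df deficits** (41% of articles): every test df in the article is
  reduced by $k \in \{1, 2, 3\}$ while the metadata keeps the described
  sample sizes — study sizes are drawn pairwise further apart than the
  maximum deficit so a deficit can never alias another study's expected
  df;
* optionally, **one-tailed** reports (halved p plus a "one-tailed" remark
  in the prose) to exercise the salvage rule.

The default per-result error rates reproduce the statistic-level
prevalences reported for real journals (≈ 6% any, ≈ 1% large, ≈ 1.2%
gross); because errors are injected independently per result, the implied
article-level prevalence at 12–19 results per article is somewhat higher
than the ≈ 45% observed in practice, where errors cluster within articles
— a known simplification. Prose templates vary spacing, italics markers
and minus signs to exercise the extraction dialects.

What passing these tests shows: the scanner recovers every result the
renderer can produce; verdicts match independent oracles; injected rates
and deficits are recovered within binomial tolerance end to end; the
inference suite is calibrated under the null. What it does not show:
performance on real PDFs/HTML (out of scope — input is plain text), on
non-APA layouts (manual entry by design), on languages other than
English, or under error mechanisms unlike the injected ones (e.g.
systematically copied-but-shifted columns of results).

## Numerical choices and degenerate inputs

Problem sizes in the test suite were chosen to keep the full run around a
minute while leaving the statistical assertions well-powered: oracle
agreement on 400 random results per unit run (10,000 in the acceptance
suite), 200-article corpora for end-to-end recovery, 200 replicates for
regression recovery, 2,000 for null calibration, 10,000 for the power
target.

Degenerate cases are pinned by tests: a zero t statistic gives p = 1;
identical samples give Wilcoxon p = 1; a zero margin gives Fisher p = 1;
all-zero counts reject the regression with a pointer to the Fisher
fallback; an empty scan returns a typed zero-row frame; a malformed
manual-entry row rejects the whole file with its row number. Interval
endpoint closures are tracked explicitly so that, for example, `p = .05`
(interval topping at .055) and `p < .05` (open at .05) land on opposite
sides of the significance filter.

## Known limitations

The extraction grammar is a dialect, not a parser of record: layouts it
does not recognise must go through manual entry, and no attempt is made to
exclude reference sections or verbatim quotations of other papers'
results. The error taxonomy cannot say *which* element of the triplet is
wrong. The df screen produces candidates, not verdicts — misprinted dfs
and unreported missingness are observationally equivalent to undisclosed
exclusion. And article-level analysis dilutes focal results with
manipulation checks and auxiliary tests; a focused analysis of each
article's central claim would need human judgement the pipeline
deliberately avoids.
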