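Package: reportcheck
Title: Consistency Checking and Error Analysis of Reported Statistical Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing the quality of statistical reporting in
    scientific articles. Extracts APA-style t and F test results from plain
    article text while preserving printed precision, recomputes p values from
    the reported test statistic and degrees of freedom, judges consistency of
    the reported p value under a rounding-aware interval rule, and classifies
    reporting errors (any, large, gross). Screens reported t-test degrees of
    freedom against described sample sizes to flag undisclosed exclusion of
    cases. Aggregates results to article level and compares article groups
    with Wilcoxon rank-sum tests, a label-reassignment permutation null for
    the rank-sum statistic, negative binomial regressions of error counts,
    Fisher exact tests, and Monte Carlo power simulation. A synthetic-corpus
    generator produces article text with known ground truth (injected
    reporting errors and degree-of-freedom deficits) so that every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
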