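Package: ncafdh
Title: Necessary Condition Analysis with CE-FDH Ceilings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Necessary Condition Analysis (NCA) for bivariate psychometric
    data using the ceiling envelopment - free disposal hull (CE-FDH)
    estimator. Computes scopes, step-function ceiling lines, the necessity
    effect size d with benchmark classification, approximate permutation
    tests, bottleneck (necessity-in-degree) tables, and prevalence/immunity
    partitions. Includes a synthetic-data generator for bounded integer
    sum-scores with a planted necessity ceiling and MCAR missingness,
    chained-equations multiple imputation with predictive-mean matching for
    sensitivity analyses, simulation-based power and minimum-sample-size
    estimation, and an end-to-end study pipeline with JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
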