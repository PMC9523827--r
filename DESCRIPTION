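Package: gsrank
Title: Group Sequential Rank Tests for the Mann-Whitney Parameter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group sequential inference for the Mann-Whitney parameter
    p = P(X1 < X2) + 0.5 P(X1 = X2) in two-arm trials with real-valued or
    ordered categorical endpoints. Implements the Wilcoxon-Mann-Whitney,
    Brunner-Munzel (normal and t-approximate) and log win odds tests with
    Lan-DeMets error-spending boundaries computed by recursive numerical
    integration of the canonical joint distribution, repeated p-values and
    repeated confidence intervals, approximate power formulas and rank-based
    sample-size search, and a seeded Monte-Carlo engine for operating
    characteristics under normal and latent-Beta ordinal data models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
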