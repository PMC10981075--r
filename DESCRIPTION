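Package: kuiperq
Title: Critical Values, Quantiles and Tests for Kuiper's Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes critical values and upper/lower tail quantiles of
    Kuiper's V_n and V_{n,n} goodness-of-fit statistics from a second-order
    asymptotic tail approximation, using direct and Newton fixed-point
    iteration.  Provides the one-sample Kuiper test against a reference
    distribution and the equal-size two-sample test, with p-values from the
    same approximation, a seeded Monte-Carlo simulator of the null
    distribution for validation, reproduction of the published critical-value
    tables (including the correction of a long-standing error in Kuiper's
    table at alpha = 0.01, n = 30), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
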