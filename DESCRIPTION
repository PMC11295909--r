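Package: primecoop
Title: Cyclical Cooperation at Prime-Numbered Rounds in Public Goods Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether cooperation in multi-round one-shot
    public goods games concentrates at prime-numbered rounds. Provides a
    synthetic-data generator emulating a 256-participant strangers-condition
    panel with random group reshuffling and provision/maintenance payoff
    framings; an evolutionary simulator of behaviour-schedule strategies
    under a pairwise-comparison (Fermi) imitation process, with predicted
    per-round cooperation curves; a per-participant autocorrelation census
    of prime-valued maximum-autocorrelation lags; a linear mixed model of
    contributions with nested random intercepts and a prime-round
    indicator; and a placebo-prime battery built by constrained
    enumeration of composite-number sets, with Euclidean-distance
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
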