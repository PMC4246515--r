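Package: betaleaf
Title: Beta Sigmoid Modelling of Grass Leaf Growth and Cell-Length Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the beta sigmoid determinate-growth function to per-leaf
    length versus thermal-time series and an extended beta sigmoid to
    cell-length versus position profiles, then extracts biologically
    relevant parameters in batch: maximal leaf elongation rate (LERmax),
    timing points (t20%, t50%, t90%, t100), leaf elongation durations
    (LEDs), steady-state growth windows, and division/elongation zone
    lengths. Includes thermal-time (growing degree day) conversion,
    alternative sigmoid families (Weibull, Gompertz, logistic) for model
    comparison, a synthetic-data generator for validation, and
    group-comparison statistics (Student t-test, ANOVA with Scheffe post
    hoc tests and compact letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
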