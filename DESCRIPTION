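Package: allopower
Title: Statistical Power of Ontogenetic Allometry Under Subsampling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how sample size limits the detection of
    ontogenetic allometry in bivariate log-log data. Fits ordinary least
    squares and standardized major axis lines with confidence-interval based
    scaling classification (positive allometry, negative allometry, hard and
    soft isometry), runs Monte-Carlo subsampling sweeps under four sampling
    schemes (random, even-length binned, even-occupancy binned, adult-biased),
    computes minimum-sample-size and false-allometry/false-isometry/sign-error
    statistics, fits hyperbolic minimum-n-versus-slope models compared by AIC
    and Akaike weights, and summarizes literature-survey sample-size
    distributions with two-sample Kolmogorov-Smirnov comparisons. Includes a
    synthetic-data generator with known allometric structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
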