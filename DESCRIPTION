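Package: fluorplex
Title: Fluorescence-First Statistical Analysis of Multiplex Bead Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Luminex xMAP-style multiplex immunoassay plate
    data directly on the median fluorescence intensity (MFI) scale. Provides a
    long-format plate data model with validation and design summaries, weighted
    five-parameter logistic (5PL) standard-curve fitting with inverse mapping and
    out-of-range censoring, limit-of-detection diagnostics (balanced
    above/below-LOD coefficient-of-variation comparisons, rank-difference
    profiles, p-value uniformity scans), global linear mixed-effects differential
    analysis with crossed random intercepts and Wald chi-square contrasts under
    Holm correction, a sigmoid-mapping simulator contrasting fluorescence-scale
    and concentration-scale two-sample t-tests, and a synthetic plate-data
    generator that emulates the design of a 37-analyte inflammation panel study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
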