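Package: chronossa
Title: Multiscale Rest-Activity Rhythm Analysis of Actigraphy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify circadian and ultradian structure in
    epoch-based actigraphy (movement counts per minute): single-harmonic
    cosinor regression with period scanning and acrophase conversion,
    intradaily variability as a function of the resampling interval IV(P),
    singular spectrum analysis (Hankel embedding, singular value
    decomposition and diagonal averaging) with day-by-day extraction of
    mesor, amplitude, acrophase and period from the reconstructed circadian
    component, power-law fits with crossover detection on the scree diagram
    of partial variances, and cohort-level nonparametric comparisons.
    Includes a synthetic actigraphy cohort generator with controllable
    day-to-day variability and an ultradian tail that is either 1/f-like or
    concentrated near a 90-minute basic rest-activity cycle.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
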