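Package: sotagree
Title: Balance Metrics and Between-Device Agreement for the Sensory
    Organization Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes center-of-pressure (COP) balance metrics from
    force-plate recordings of quiet stance -- the estimated equilibrium
    index, 95% confidence-ellipse sway area, sway path length, and the
    anterior-posterior detrended fluctuation analysis scaling exponent --
    and quantifies between-device agreement per sensory organization test
    (SOT) condition with two-way intraclass correlations (absolute
    agreement and consistency), Pearson correlations, and Bland-Altman
    limits of agreement.  Includes plain-text trial I/O, a paired-session
    synthetic study generator with a tunable latent device agreement, and
    an end-to-end pipeline with trial selection and 3-SD paired outlier
    screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
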