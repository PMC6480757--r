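Package: mentalspeed
Title: Scoring and Response-Time Modelling for Mental Speed Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for individual-differences research on
    mental speed. Implements trial-level screening (liberal Tukey fences,
    200 ms floor, post-error exclusion), a battery of alternative response-time
    scores (reciprocal speed, central tendency, quantiles, variability, error
    rates with probit transformation, cross-person winsorization),
    ex-Gaussian distribution fitting (maximum likelihood and a two-step
    kernel/bootstrap estimator) with quantile-based fit diagnostics,
    EZ diffusion-model inversion with a Wiener first-passage simulator as
    oracle, attentional-blink and recall-1-back working-memory scoring, and
    worst-performance-rule RT-band analyses with Fisher-z confidence intervals
    and attenuation-corrected correlations. A synthetic trial-level generator
    with a person-level latent-trait structure makes every pipeline stage
    verifiable by parameter-recovery simulation.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
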