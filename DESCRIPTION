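Package: ibpcog
Title: Indian Buffet Process Latent Feature Analysis of Neurocognitive Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a linear-Gaussian Indian Buffet Process (IBP) to a
    standardized multi-task neurocognitive battery to discover
    individual-specific binary latent features, with a missing-data-aware
    Gibbs sampler, hyperparameter resampling and continuous (probability
    scale) feature-value extraction. Downstream tools filter features by
    sampling count, profile them as mean z-scores per measure, test
    demographic balance, assess split-half stability, and compare feature
    correlations with behavioral outcomes using overlapping
    dependent-correlation tests (Steiger/Dunn-Clark z, Williams t, Zou
    confidence interval) with family-wise Bonferroni correction. A synthetic
    data generator with planted ground truth supports parameter-recovery
    and calibration studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
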