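Package: popdecode
Title: Maximum-Likelihood Population Decoding and Synaptic Weight Heterogeneity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how the functional
    diversity of excitatory synaptic inputs onto cortical neurons follows from
    probabilistic population decoding. Builds orientation-tuned input
    populations with limited-range noise correlations and Poisson-like
    variance scaling, derives the analytic maximum-likelihood (softmax)
    readout weights in closed form, resamples positive decoder weights into
    synthetic synaptic input populations, and generates and quality-controls
    synthetic dendritic-spine calcium-imaging datasets so that input-output
    tuning-correlation distributions, Kullback-Leibler model comparisons, and
    trial-variability statistics can be reproduced end-to-end on synthetic
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
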