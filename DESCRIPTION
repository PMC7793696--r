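Package: smrcoh
Title: Simulation and Analysis of SMR-Coherence Neurofeedback Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse closed-loop EEG neurofeedback
    training on sensorimotor-rhythm (SMR, 12-15 Hz) coherence between a
    Cz-CPz channel pair. Provides a synthetic two-channel EEG generator
    with controllable band-limited coupling, lag, 1/f background, theta
    and beta components, and ocular/muscle artifacts; epoch-based artifact
    rejection; epoch-averaged cross-spectral estimation with
    magnitude-squared and imaginary coherence and complex-demodulation
    band power; a simulator of the ten-session training protocol with
    baseline-derived thresholds, per-run threshold adaptation and reward
    counting; and the trend statistics used to quantify learning
    (linear mixed-effects session/run models with Satterthwaite degrees
    of freedom, Cousineau-Morey within-subject standard errors, paired
    pre/post tests with Bonferroni correction, and per-strategy slope
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    tibble,
    dplyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
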