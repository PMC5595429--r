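Package: recmem
Title: Dual-Process Analysis of Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of recollection and familiarity from trial-level
    recognition-memory data using three independent procedures: maximum
    likelihood fitting of the Yonelinas dual-process signal-detection
    (high-threshold) model to confidence-rating ROC data, the process
    dissociation procedure on associative word pairs, and
    Remember/Know/Guess attribution with the independence correction.
    Includes the equal-variance signal-detection core (Snodgrass-Corwin
    corrected rates, d-prime, criterion c), cross-task z-score summaries
    against a control group, small-sample nonparametric group statistics
    (Mann-Whitney U, exact and Monte Carlo permutation tests, Spearman
    correlation, the Vargha-Delaney A measure of stochastic superiority,
    Bonferroni-Holm adjustment), a trial-level generative simulator with
    known latent parameters for parameter-recovery studies, and an
    end-to-end scoring and group-comparison pipeline for patient/control
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
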