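Package: chordexpect
Title: Cognitive and Sensory Models of Harmonic Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and compares cognitive and sensory computational
    models of musical expectancy against continuous chord-wise behavioural
    ratings. Implements a variable-order Markov (PPM) chord model emitting
    information content and entropy under cross-validated long-term and
    online short-term components; sensory expectancy via spectral pitch-class
    distance and a periodicity-pitch auditory short-term memory model;
    preprocessing of continuous slider ratings into per-chord observations;
    Bayesian multilevel Gaussian regression with song-level varying effects
    and AR(1) residuals fitted by a blocked Gibbs sampler; model comparison
    by Pareto-smoothed importance-sampling leave-one-out cross-validation
    (PSIS-LOO) and Bayesian stacking; and a synthetic-data generator that
    emulates the chord corpora, stimuli and raters the analysis assumes.
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
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
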