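Package: protean
Title: Escape-Trajectory Analysis via Structure Functions, Straightness
    and Directional Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing regularly sampled two-dimensional animal
    trajectories from two-treatment escape experiments. Computes per-path
    kinematics (mean speed, initial and final headings, turning angles,
    windowed straightness index), characterises anomalous diffusion through
    qth-order structure functions and their scaling exponents zeta(q) with a
    single summary slope on the Brownian-to-ballistic continuum, quantifies
    path unpredictability as the Shannon entropy of binned turning angles,
    and tests angular uniformity with the Rayleigh test. Group comparisons
    follow the study design they were developed for: one-way linear models,
    a heteroscedastic (variance-per-group) generalised least squares fit
    with likelihood-ratio inference, Levene's test, and an entropy ANCOVA.
    A synthetic-trajectory generator (Brownian, correlated random walk,
    Levy, ballistic) with a two-treatment study simulator makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
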