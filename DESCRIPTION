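Package: ampscale
Title: Whole-Cell Balanced Synaptic Amplification: Miniature-Event
    Statistics, Fluctuation Analysis and Single-Neuron Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whole-cell balanced synaptic amplification,
    a model in which the conductance of every AMPA and GABA-A synapse on a
    neuron is doubled at once.  The package generates synthetic miniature
    postsynaptic current (mEPSC/mIPSC) data sets with known ground truth;
    quantifies per-cell blocker effects, segregates affected cells by
    two-means clustering, estimates the fraction of events affected by a
    blocker, and reverses blocker effects under competing generative models
    with permutation Cramer-von Mises tests; estimates single-channel
    current and channel count by peak-scaled non-stationary fluctuation
    analysis (NSFA); simulates a conductance-based three-cylinder pyramidal
    cell under Poisson synaptic bombardment with a compiled cable
    integrator, including voltage clamp, whole-cell conductance scaling and
    alpha-function rate bumps; and evaluates the closed-form shot-noise
    variance and Gaussian threshold-linear firing-rate theory that predict
    the amplification factor, with protocol drivers that orchestrate the
    paired pre/post-amplification experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    cluster,
    lhs,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
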