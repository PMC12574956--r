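Package: hcspike
Title: Highly Comparative Analysis of Multineuron Spike Train Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generators for synthetic multineuron spike trains with
    controlled synchrony, rhythmicity and sequential structure
    (inhomogeneous-Poisson and doubly stochastic event-based families),
    a library of univariate, bivariate, multivariate and spectral spike
    train measures (Victor-Purpura, van Rossum, SPIKE- and ISI-distance,
    spike time tiling coefficient, correlation index, phase consistency,
    Golomb-Rinzel synchrony, aperiodic/periodic spectral parameterization,
    and others), and a highly comparative evaluation framework: benchmark
    grids, measure-parameter correlation profiles, hierarchical clustering
    of measures, finite-sample bias and variability estimation, windowed
    recording fingerprinting, two-class discriminability decoding, and
    intrinsic dimension estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    cluster,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
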