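Package: corrperc
Title: Correlated Site Percolation in Growing Bacterial Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation and statistical analysis of correlated
    electrical-signal percolation in a growing bacterial biofilm monolayer.
    Cells occupy a finite six-neighbor (triangular) lattice and carry a
    binary signaling state inherited at division with a tunable correlation;
    the package provides the event-driven growth simulator, spanning
    connectivity and cluster-size statistics, discrete power-law maximum
    likelihood fitting, spatial autocorrelation of binary cell fields with
    randomized controls, renormalization (site-decimation) checks of the
    inheritance Markov chain, and a synthetic-microscopy pipeline
    (rendering, thresholding, median filtering, majority-area cluster
    counting) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
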