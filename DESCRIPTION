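Package: meboundary
Title: Adaptive Vertex-Model Simulation and Quantification of the
    Drosophila Mesectoderm-Ectoderm Boundary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mesectoderm-ectoderm (ME) boundary of the early
    Drosophila embryo with an adaptive two-dimensional vertex model that
    couples a decaying actomyosin line tension at the heterotypic interface,
    apical constriction of the mesectoderm via a shrinking preferred area,
    and stochastic oriented cell divisions in the ectoderm, integrated with
    Brownian overdamped vertex dynamics. Provides the quantification layer
    used to analyse both simulations and tracked-cell data: boundary
    roughness and its area-under-the-curve statistic, the self-overlap
    function and its half-time, mean squared displacement with axis
    decomposition and mesectoderm registration, junctional tension from
    energy gradients, Kelvin-Voigt fitting of post-ablation recoil curves,
    synthetic-data generators with known ground truth, and non-parametric
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
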