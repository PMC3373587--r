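Package: ssenoise
Title: Intrinsic Noise Analysis of Biochemical Reaction Networks by the
    System Size Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring intrinsic noise in well-mixed biochemical
    reaction networks. Builds reaction networks programmatically or from a
    supported SBML subset, constructs the van Kampen system size expansion
    of the chemical master equation by exact symbolic differentiation, and
    solves the macroscopic rate equations, the linear noise approximation
    (LNA) and the effective mesoscopic rate equations (EMRE) in time-course
    and steady-state modes. Predictions can be cross-validated against
    built-in exact stochastic simulation (Gillespie direct and optimized
    direct methods) with reproducible streaming ensemble statistics.
    Includes programmatic reconstructions of classic example models of
    enzyme kinetics and circadian gene expression, and a command line
    interface for batch analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    xml2,
    stats,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    parallel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
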