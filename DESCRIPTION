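Package: cyclizer
Title: DNA Cyclization J-Factors from Breathing-Coupled Rigid Base-Pair Monte Carlo
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates Jacobson-Stockmayer J-factors of DNA sequences by Monte
    Carlo simulation of rigid base-pair chains with sequence-dependent
    trinucleotide equilibrium geometry, in two modes: the classical
    Czapla-Swigon-Olson (CSO) chain model, and a breathing-coupled mode in which
    per-base-pair opening probabilities from an extended Peyrard-Bishop-Dauxois
    (EPBD) nonlinear-lattice Metropolis sampler supply transient single-stranded
    "flexible hinges" with enlarged angular fluctuations. Includes the EPBD
    sampler itself, closure-observable accumulation with the three-factor
    ring-closure estimator, persistence-length estimation, benchmark statistics
    against experimental J-factors, and synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
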