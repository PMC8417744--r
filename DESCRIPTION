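Package: synerflux
Title: Drug-Combination Synergy Screening and Isotope-Tracer Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage drug-synergy discovery analytics for acute myeloid
    leukemia screens. Implements Bliss-independence viability scoring with
    Dixon's Q replicate filtering and two-criterion hit selection for primary
    ATP-bioluminescence screens; direct-infusion mass-spectrometry feature
    cleaning (ppm annotation, replicate/blank/sample filters, random-forest
    imputation, probabilistic quotient normalization); a PCA-based Euclidean
    distance synergy (PEDS) statistic for multivariate metabolomic profiles;
    stable-isotope-tracer arithmetic (natural-abundance correction, mass
    isotopomer distribution vectors, enrichment summaries); and steady-state
    metabolic flux analysis on atom-mapped networks via elementary metabolite
    unit (EMU) simulation with Metropolis-Hastings posterior sampling and
    Cohen's-d flux-ratio comparisons. A synthetic-data generator emulates
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
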