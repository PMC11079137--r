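Package: hypoxsel
Title: Codon-Model Selection Analysis and Convergent Substitution Detection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood analysis of selective pressure on protein-coding
    genes under Goldman-Yang codon substitution models: one-ratio, free-ratio and
    habitat-partitioned multi-ratio branch models, M8/M8a site models and the
    branch-site model A, with nested likelihood-ratio tests and Bayes empirical
    Bayes identification of positively selected sites. Includes marginal ancestral
    sequence reconstruction, detection and Poisson testing of parallel and
    convergent amino-acid substitutions between focal lineages, and a codon
    alignment simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
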