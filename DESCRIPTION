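Package: ohnoconv
Title: Detecting Interlocus Gene Conversion Among Whole-Genome-Duplication Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Likelihood-based detection of interlocus gene conversion between
    paralogs retained from a whole-genome duplication (ohnologs). Implements a
    protein-identity candidate screen, a triplet branch-specific Ka/Ks
    relative-rate likelihood-ratio test, a species-tree versus
    gene-conversion-tree comparison with parametric-bootstrap significance, and
    a similarity-groups codon model separating radical from conservative amino
    acid substitution constraints. Includes a Muse-Gaut/Goldman-Yang codon
    substitution engine (pruning likelihood, maximum-likelihood fitting,
    sequence simulation) and a synthetic post-WGD gene-family generator with
    known conversion ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
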