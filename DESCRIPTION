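Package: mitosel
Title: Selection Scans and Statistical Coupling Analysis for
    Mitochondrial Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution models (the M-series
    site models M0-M8 and branch-site Model A) for detecting positive
    Darwinian selection in mitochondrial protein-coding genes, with
    likelihood-ratio tests and naive/Bayes empirical Bayes identification
    of positively selected sites.  A second track implements a modified
    statistical coupling analysis of amino-acid alignments: per-site
    statistical energies against a reference residue distribution,
    perturbation-based coupling energies, and alignment-suitability
    diagnostics.  Includes simulators for codon alignments evolved under
    mixture and branch-site models and for amino-acid alignments with
    planted column couplings, so the whole pipeline can be exercised on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
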