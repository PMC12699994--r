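Package: topictree
Title: Alignment-Free Phylogenetics from k-mer Topic Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers species and population trees from multilocus DNA
    sequences without alignment. Sequences are decomposed into
    non-overlapping k-mers, a latent Dirichlet allocation topic model is
    fitted to each locus, and the per-taxon topic frequencies are treated
    as continuous characters evolving by Brownian motion; an unrooted tree
    is then estimated by restricted maximum likelihood with stepwise
    addition and nearest-neighbor-interchange search. Includes k-mer-level
    and site-level bootstrapping with majority-rule consensus,
    Robinson-Foulds tree comparison, and a sequence simulator with
    insertions and deletions for method evaluation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    seqinr,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
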