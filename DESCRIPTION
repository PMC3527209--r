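Package: cosmotracts
Title: Detection of Cosmopolitan Admixture Tracts in African Drosophila
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects tracts of cosmopolitan (out-of-Africa) ancestry in
    sub-Saharan Drosophila melanogaster haploid genome sequences using a
    two-state hidden Markov model with empirical, divergence-based
    emission distributions.  Includes identity-by-descent masking of
    related genome pairs, SNP-count windowing of chromosome arms,
    iterative refinement of the African reference panel, a coalescent
    plus forward Wright-Fisher simulation harness that generates admixed
    genomes with known tract locations for validation, windowed
    population-genetic summary statistics (nucleotide diversity, relative
    diversity, D_xy, Hudson's F_ST, folded site frequency spectra,
    directional linkage disequilibrium), a bootstrap diversity-ratio
    test, and windowed outlier-region scanning with gene-ontology
    permutation enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
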