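Package: mpbwt
Title: Multi-Allelic Positional Burrows-Wheeler Transform for Haplotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of positional prefix and divergence arrays over
    phased haplotype panels with arbitrary per-site allele alphabets, using a
    t-way counting-sort sweep. Reports all pairwise haplotype matches of at
    least a given site length and set-maximal matches, including matches that
    run to the end of the panel, which the classical bi-allelic formulation
    misses. Provides a positional FM-index transform with run-length encoded
    storage and exact panel reconstruction via the extension (rank) function,
    plus a self-contained haplotype panel simulator with linkage
    disequilibrium-like block structure and multi-allelic site conversion for
    validation. Panels are read from plain allele matrices or phased VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    vcfR,
    withr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
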