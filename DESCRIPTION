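Package: oscan
Title: Out-of-Frame Stop Codon Analysis in Prokaryotic Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts and characterises out-of-frame (hidden) stop codons in
    annotated prokaryotic coding sequences, and tests each genome for over-
    or underrepresentation of hidden stops against Monte Carlo null models.
    Null sequences are generated from nested compositional models fitted to
    the genome itself: codon-usage, dipeptide and dicodon chains, and second-
    or fifth-order three-periodic nucleotide Markov models. The package also
    provides the accompanying descriptive analyses (per-frame densities and
    frame bias, stop-usage principal components, proportional marginal
    variance decomposition of regressor importance, stepwise model selection)
    and a synthetic-genome generator with controllable G+C content, codon and
    dicodon bias, and an optionally planted hidden-stop excess.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
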