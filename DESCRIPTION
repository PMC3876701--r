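Package: phagecensor
Title: Error Analysis and Censorship Detection for Deep-Sequenced
    Phage-Display Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents a deep-sequenced phage-display peptide library as a
    sequence multiset (an ordered set of unique sequences with a copy-number
    vector), models stochastic sampling of the library as draws from the
    multivariate hypergeometric distribution, and estimates per-sequence
    Monte-Carlo confidence intervals for the outcome of sampling. On top of
    this machinery the package parses amplicon FASTQ reads, applies
    Phred-quality read filtering, and detects sequence-specific censorship:
    statistically significant loss of specific sequences during quality
    filtering, beyond what random sampling explains. A synthetic library and
    FASTQ generator with planted censorship provides ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
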