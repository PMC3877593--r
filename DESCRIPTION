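Package: intronhex
Title: Conservation and Mutation of Splice-Site Hexanucleotides in
    Orthologous Intron Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative analysis of the intronic initial (5' splice site)
    and terminal (3' splice site) hexanucleotides in pairs of orthologous
    introns from two species. Computes per-position cross-species identity
    profiles over the intron ends, hexanucleotide usage censuses and
    per-position base composition, a random-association null model of
    nucleotide conservation with exact one-tailed binomial tests for
    over- and under-represented splice-site motifs, ungapped U1 snRNA
    complementarity scores for 5' splice sites, and classification of
    transcript variants (exon skipping, alternative 3'/5' splice sites)
    against canonical transcript structures. Includes a seeded generator
    of synthetic orthologous intron couples with configurable ancestral
    hexanucleotide usage, per-position conservation and intron-body
    identity plateaus, so the whole pipeline is testable without external
    sequence downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
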