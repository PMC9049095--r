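Package: cubkit
Title: Codon Usage Bias Analysis of Coding Sequences
Version: 0.1.0
Authors@R: person("cubkit", "developers", email = "cubkit@example.org",
    role = c("aut", "cre"))
Description: Tools for codon usage bias analysis of protein-coding
    sequences: coding-sequence validation, nucleotide composition and
    positional GC content, the effective number of codons (ENc), relative
    synonymous codon usage (RSCU) with over/under-representation classes,
    the codon adaptation index (CAI), GRAVY and aromaticity of the encoded
    proteins, neutrality-plot and parity-rule-2 diagnostics of mutation
    pressure versus selection, correspondence analysis of gene-by-codon
    RSCU matrices, neighbor-joining clustering of RSCU profiles, and
    chi-square classification of adjacent codon-pair context. A synthetic
    coding-sequence generator with controlled compositional regimes
    supports testing every stage without external downloads, and a
    pipeline driver orchestrates the full analysis from FASTA to a table
    bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr
Config/testthat/edition: 3
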