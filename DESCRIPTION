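Package: cpcodon
Title: Codon Usage Bias and Quadripartite Structure Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias and structural features of
    chloroplast (plastid) genomes. Reads annotated genomes in GenBank flat-file
    format, extracts and filters protein-coding sequences, and computes the
    standard codon-usage statistics: positional GC content (GC1/GC2/GC3),
    relative synonymous codon usage (RSCU), Wright's effective number of codons
    (ENC) and its expected value under mutation alone, PR2 parity coordinates,
    neutrality-plot regression, ENC-plot diagnostics, and optimal-codon
    identification from high- and low-expression gene groups. Also detects the
    quadripartite LSC/IRb/SSC/IRa architecture of circular plastomes, reports
    genes at inverted-repeat junctions, and scans alignments for nucleotide
    diversity (pi) to call hypervariable regions. Includes seeded generators
    for synthetic coding sequences, genomes and alignments with known ground
    truth, used throughout the test suite.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
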