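Package: ctdnaIntegrate
Title: Detection of Circulating Tumor DNA Integration in Cocultured Cell Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for detecting circulating tumor DNA
    (ctDNA) fragments integrated into a recipient cell genome under coculture.
    Provides a desk-scale simulator of the cell/ctDNA/coculture experimental
    design (adaptor-ligated cfDNA fragments, planted insertions with a
    proximity bias, coculture-unique duplications, paired-end reads, transgene
    cassettes), a transparent pileup SNV caller with three-way variant set
    logic ("SNVs of interest"), chimeric-contig transition-point detection with
    ctDNA-origin confirmation by private SNVs, duplication calling,
    transposable-element annotation against a consensus library with
    transition-window filtering, chi-square TE enrichment and tissue
    specificity tests, and a discordant read-pair transgene insertion caller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
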