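Package: posmap
Title: Positional RNA-Binding Protein Motif Maps Around Differentially Used Exons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying position-dependent splicing regulation by an
    RNA-binding protein. Provides a seeded simulator of cassette-exon genomes
    with negative-binomial exon-bin counts and motifs planted at controlled
    offsets; a pooled-count differential exon-usage test with TPM, fold-change
    and FDR filtering and activated/repressed exon classification; strand-aware
    extraction of intronic and exonic windows flanking exons; IUPAC degenerate
    motif scanning with foreground/background enrichment ranking; inference of
    activator- versus repressor-type positional binding from upstream/downstream
    motif asymmetry; and comparison of splicing programs across conditions,
    including detection of exons that revert to a reference (embryonic) state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
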