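Package: sosdep
Title: Predict Prophage SOS Dependency by LexA Operator Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies prophages in bacterial genomes as SOS-dependent,
    SOS-independent, or SOS-uncertain from sequence alone. Candidate LexA
    operators (SOS boxes) are located by a strand-aware core-motif scan and
    scored with the Berg-von Hippel heterology index (HI) against a position
    count matrix; genome-specific binding thresholds are derived by clustering
    the genome-wide HI distribution (mean shift by default); each prophage is
    then called by comparing the minimum HI over its promoter regions against
    those thresholds. Includes exact binomial validation statistics,
    phage-versus-host genomic feature comparisons (coding density, CDS
    overlap, intergenic GC, codon and k-mer usage distances), and a seeded
    synthetic-genome generator with planted operators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
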