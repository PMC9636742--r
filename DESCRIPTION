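Package: epilnc
Title: Epimutation-Anchored Discovery of Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of candidate long non-coding RNAs (lncRNAs) anchored at
    single-CpG epimutations. Reads per-sample bisulfite methylation call files
    (bismark-coverage or bedGraph dialect) into a site-by-sample count matrix,
    calls differential single-CpG epimutations between case and control groups
    with a pooled two-sided Fisher exact test and Benjamini-Hochberg adjustment,
    proposes MS-HRM-suitable candidate primer regions around top sites, anchors
    assembled transcript models (GTF) at the called positions, and screens the
    anchored transcripts through a six-criterion noncoding filter cascade:
    length, open reading frame length, PFAM hit ingestion, external noncoding
    score ingestion, a built-in CPAT-style coding-probability model (Fickett
    TESTCODE, hexamer usage bias, logistic regression), and annotation flank
    removal with an antisense exemption. Expression is reported as RPKM. A
    seeded synthetic-data generator produces complete fixtures (genome,
    annotation, methylation counts with planted epimutations, transcripts with
    planted coding or noncoding character, reads) for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
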