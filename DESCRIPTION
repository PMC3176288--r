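Package: mirmeth
Title: Bisulfite Clone Methylation, Dual-Mapper Expression Consensus and
    Methyl-DIP Enrichment for Epigenetically Regulated miRNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the epigenetic regulation of miRNA genes
    in melanoma-style study designs. Implements in-silico bisulfite
    conversion and bisulfite PCR, per-clone CpG methylation calling with
    conversion-efficiency quality control, clone-matrix construction and
    hypermethylation classification of CpG islands; a dual-mapper RPKM
    consensus differential-expression procedure with pseudo-count fold
    changes, transcript-delta cutoffs and ranked target-list filtering;
    interval-level RPKM quantification of methylated-DNA enrichment
    (Methyl-DIP) experiments; quantitation of adhesion, Matrigel invasion
    and wound-healing assays with an exact-permutation Kruskal-Wallis test
    and comparative-Ct relative quantification; and seeded synthetic-data
    generators that emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
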