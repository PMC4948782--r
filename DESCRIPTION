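Package: ctdnafrag
Title: Fragment-Length Analysis and In Silico Size Selection for Circulating Tumor DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cell-free DNA (cfDNA) fragmentomics: a synthetic cfDNA
    cohort simulator built on a nucleosome-ladder fragment-length mixture, a
    dual-genome (xenograft) species-of-origin read-pair classifier with
    tumor-DNA abundance estimation, fragment-length profiling from paired-end
    alignments (modal length, ~10 bp periodicity, allele-stratified lengths,
    binned mutant-allele frequency), in-silico size selection with
    mutant-allele enrichment and window scanning, duplex molecular-barcode
    family collapsing with gene-level copy number from unique depth, and
    exact-match in-silico PCR for ladder design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
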