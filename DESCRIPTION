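Package: hydroseq
Title: Modification Profiling of tRNA Hydrolysis-Fragment Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for tRNA-HydroSeq style experiments, in which limited
    alkaline hydrolysis fragments of purified tRNA (19-35 nt) are sequenced
    and base modifications are read out as reverse-transcriptase
    misincorporation signatures. Builds deduplicated two-tier references
    (unique mature tRNA sequences and unique precursor gene sequences) with
    canonical (Sprinzl-style) position numbering from a genome FASTA plus
    tRNA gene annotation; maps fragments hierarchically (mature tier first,
    then precursor) with a mismatch-tolerant ungapped aligner; tabulates
    per-position misincorporation fractions from uniquely mapped reads;
    classifies Trm1 targets from G26 signals and compares conditions with
    paired tests; produces fractional-weight count tables with
    median-of-ratios normalization; simulates libraries with ground-truth
    modification states; and implements northern-blot PHA quantification
    formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
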