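Package: BACends
Title: Restriction-Site Split-Read Profiling of BAC-End Junction Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling large-insert (BAC) clone libraries from
    short-read sequencing of restriction-digested, self-ligated end
    junctions. Reads carrying a restriction enzyme recognition site are
    selected and split into flanks, flank alignments against a reference
    genome are paired and classified (same chromosome, different
    chromosome, unmapped), same-chromosome junctions are subtyped as
    clone-end or internal-fragment circularization by orientation, and
    internal gaps (the genomic span between the two flanks) are binned
    into library-quality and physical-map-anchor reports. Includes in
    silico restriction digestion, a toy exact-match aligner, and a
    synthetic BAC-end library simulator with full ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
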