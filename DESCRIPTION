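Package: rtdetect
Title: Detection and Characterization of Balanced Reciprocal
    Translocations from Paired-End Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects balanced reciprocal translocations (RTs) from
    paired-end short-read sequencing data. Implements inter-chromosomal
    breakend calling from discordant read pairs and split reads, tiered
    quality filtering, reciprocal-pair matching by connection type,
    automated breakpoint-pattern classification (RT-like versus
    repeat-artifact loci), and base-pair-resolution junction
    characterization (microhomology, blunt-end ligation,
    micro-insertion, bases lost, derived-chromosome arithmetic, gene
    context). Ships a diploid RT-carrier read simulator with truth
    alignments, interspersed-repeat confounders and coverage
    subsampling so the whole pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
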