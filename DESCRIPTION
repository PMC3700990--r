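Package: srnadeg
Title: Small RNA and Degradome Profiling with Exact-Match Mapping
Version: 0.1.0
Authors@R:
    person("Mara", "Keller", email = "m.keller@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide small-RNA and degradome
    (PARE) sequencing analysis in organisms without a finished genome:
    demultiplexing, adapter trimming, size selection and rRNA/tRNA/plastid
    decontamination of reads; full-length 100%-identity mapping to genome
    contigs, predicted coding sequences and EST contigs on both strands;
    length and 5'-base profiling and hotspot detection; degradome-based
    transcript orientation and sense/antisense strand-bias classification
    of exonic small RNAs; 5'-end cleavage pileups with a 3x-above-mean peak
    caller, randomized peak controls and a permutation overlap test; and
    RPKM-based differential expression filtering across stress conditions.
    Includes a read simulator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
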