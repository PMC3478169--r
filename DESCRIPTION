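Package: multika
Title: Post-Assembly Processing for Multiple-k De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke post-assembly stages of a multiple-kmer de
    novo transcriptome project: quality trimming of short paired-end reads to
    the longest contiguous high-quality segment, per-locus representative
    transcript selection from Oases-style assemblies, additive multiple-k
    merging by greedy 95 percent identity clustering, read-coverage based
    removal of low-coverage and chimeric (coverage-gap) transcripts,
    microsatellite and repeat-landscape scanning, BLAST tabular annotation
    merging, and assembly summary statistics (N50 and friends). Includes a
    synthetic-data generator that emits ground-truth transcriptomes, multi-k
    pseudo-assemblies, simulated reads and planted defects so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
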