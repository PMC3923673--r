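Package: ploidyscape
Title: Genome Landscape Analysis of Hybrid Yeast Isolates from Windowed
    Allele Balance and Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers base ploidy of hybrid (allopolyploid) yeast genomes from
    sliding-window major-allele frequencies, detects loss-of-heterozygosity
    (LOH) and copy-number variation from windowed read depth using a
    21-window segmental-smoothing rule with a +/-0.75 change threshold,
    classifies LOH mechanism (gene conversion versus heterozygous deletion)
    by co-localisation with copy-number state, detects strain-specific
    deletions against gene annotations, and assembles per-locus haplotypes
    from SNPs co-occurring within individual reads.  A synthetic
    allotriploid-genome simulator with planted LOH, CNV and deletion events
    provides ground truth for recovery tests, standing in for short-read
    resequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
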