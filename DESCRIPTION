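Package: estsnp
Title: EST-Derived SNP Discovery and Validation for Partially Duplicated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to mine candidate single nucleotide polymorphisms (SNPs)
    from expressed sequence tag (EST) contig alignments with stringent
    depth, minor-count and flank-conservation filters, to select a
    genotyping validation panel (spacing, flank-length, genomic-contiguity,
    design-score and similarity filters), and to classify assayed SNPs as
    failed, monomorphic, paralogous sequence variants (PSVs) or true SNPs
    using doubled-haploid individuals as a duplication detector, with
    multisite variant (MSV) candidate flagging. Includes population-genetic
    summaries (expected heterozygosity, polymorphism information content,
    minor-allele-frequency bins, transition/transversion tables),
    synonymous/non-synonymous annotation of coding SNPs from tabular
    homology hits, and a ground-truth-labelled simulator of a partially
    duplicated, salmonid-like pseudo-tetraploid gene set so that every
    pipeline stage can be tested end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
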