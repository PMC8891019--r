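Package: crypticex
Title: Quantification of TDP-43-Dependent Cryptic Exon Inclusion in UNC13A
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies cryptic-exon (CE) inclusion in UNC13A from
    spliced RNA-seq alignments. Implements junction extraction from CIGAR gaps
    with duplicate, mapping-quality and overhang filters, model-relative junction
    classification, sample-suitability gating, CE-positive calling, inclusion
    fraction and junction PSI statistics, allele-specific CE inclusion from
    amplicon reads with a paired imbalance test, genotype-independence chi-square
    linkage-disequilibrium tagging, CATC-repeat dosage, risk-haplotype dose
    coding and dose-abundance regression. A simulation module generates spliced
    SAM alignments, amplicon reads, genotype VCFs and abundance tables with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
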