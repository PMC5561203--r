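Package: baitforge
Title: Hybridization-Capture SNP Chip Design and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design pipeline for solution-hybrid-selection (SHS) target-enrichment
    SNP chips. Reduces a cohort VCF to biallelic candidate SNPs with GATK-style
    hard filters and depth/missingness rules, screens 150-bp SNP flanks for
    hairpin structures, k-mer non-uniqueness and repeat overlap, enumerates and
    selects 90-bp capture baits embedded in 120-mer oligos with PCR arms, thins
    chip density to a 40-kb target spacing with a triangular MAF-weighted window
    score, and computes capture-evaluation metrics (on/off-target accounting,
    per-target depth profiles, coverage uniformity, GC-depth tables, cross-run
    SNP concordance) from alignments. Ships a deterministic synthetic-data
    generator with planted, known truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
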