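# Shared small synthetic study, built once per test run. 60 SNP loci on a
# 150-kb contig with planted defects: 8 hairpin flanks, 5 duplicated flanks,
# 4 in-repeat SNPs, 3 sites per hard-filter clause.
small_config <- function(seed = 42L) {
  synthetic_config(seed = seed, contig_len = 150000L, n_snps = 60L,
                   n_hairpin = 8L, n_dup = 5L, n_repeat = 4L,
                   n_per_clause = 3L, n_individuals = 40L)
}

.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- small_config()
    g <- make_genome(cfg)
    vcf <- make_cohort_vcf(g$genome, g$truth, cfg)
    .fixture_env$study <- list(cfg = cfg, genome = g$genome,
                               repeats = g$repeats, truth = g$truth,
                               vcf = vcf, index = kmer_index(g$genome))
  }
  .fixture_env$study
}
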