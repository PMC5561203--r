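rec <- function(info = numeric(), gt = c(0L, 1L), dp = NULL) {
  variant_record("c", 100, "A", "G", info = info, genotypes = gt,
                 sample_depths = dp)
}

test_that("hard filter fails on any triggering clause, passes absent keys", {
  expect_false(apply_hard_filter(rec(c(QD = 1.5)))$pass)
  expect_identical(apply_hard_filter(rec(c(QD = 1.5)))$reasons, "HARD_FILTER")
  expect_true(apply_hard_filter(rec())$pass)          # all keys absent
  expect_false(apply_hard_filter(rec(c(FS = 60.1)))$pass)
  expect_false(apply_hard_filter(rec(c(MQRankSum = -12.6)))$pass)
  expect_false(apply_hard_filter(rec(c(ReadPosRankSum = -8.1)))$pass)
  # GWA-side configuration: stricter QD plus HaplotypeScore clause
  t2 <- filter_thresholds(qd_min = 4.0, haplotypescore_max = 13.0)
  expect_false(apply_hard_filter(rec(c(QD = 3.5)), t2)$pass)
  expect_false(apply_hard_filter(rec(c(HaplotypeScore = 14)), t2)$pass)
  expect_true(apply_hard_filter(rec(c(HaplotypeScore = 14)))$pass)
})

test_that("hard filter verdicts equal a literal re-evaluation on random records", {
  set.seed(5)
  for (i in 1:200) {
    keys <- sample(c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
                   sample(0:5, 1))
    vals <- setNames(runif(length(keys), -20, 80), keys)
    got <- apply_hard_filter(rec(vals))$pass
    expect_identical(got, !oracle_hard_filter_fails(vals))
  }
})

test_that("site depth bounds are inclusive, with sum-of-depths fallback", {
  expect_true(site_depth_filter(rec(c(DP = 80)))$pass)
  expect_false(site_depth_filter(rec(c(DP = 79)))$pass)
  expect_true(site_depth_filter(rec(c(DP = 1000)))$pass)
  expect_false(site_depth_filter(rec(c(DP = 1001)))$pass)
  r <- rec(gt = rep(0L, 3), dp = c(40L, 40L, 40L))   # no DP key, sum = 120
  expect_true(site_depth_filter(r)$pass)
  r2 <- rec(gt = c(0L, 1L))                          # no depth information
  expect_identical(site_depth_filter(r2)$reasons, "DEPTH_RANGE_UNKNOWN")
})

test_that("missingness filter triggers strictly above 20% on either fraction", {
  r <- rec(gt = c(rep(0L, 7), NA, NA, NA), dp = rep(10L, 10))
  expect_identical(missingness_filter(r)$reasons, "MISSINGNESS")
  r2 <- rec(gt = c(rep(0L, 8), NA, NA), dp = c(rep(10L, 8), 1L, 1L))
  expect_true(missingness_filter(r2)$pass)          # both exactly 0.20
  r3 <- rec(gt = rep(0L, 10), dp = c(rep(10L, 7), 0L, 1L, 1L))
  expect_identical(missingness_filter(r3)$reasons, "LOW_DEPTH_SAMPLES")
  # literal conjunction mode: one trigger alone is not enough
  t_both <- filter_thresholds(missingness_mode = "both")
  expect_true(missingness_filter(r, t_both)$pass)
  r4 <- rec(gt = c(rep(0L, 7), NA, NA, NA), dp = c(rep(1L, 3), rep(10L, 7)))
  expect_false(missingness_filter(r4, t_both)$pass)
})

test_that("missingness verdicts match a direct recount on random cohorts", {
  set.seed(9)
  t <- filter_thresholds()
  for (i in 1:50) {
    n <- sample(5:50, 1)
    gt <- sample(c(0L, 1L, 2L, NA), n, TRUE)
    dp <- sample(0:20, n, TRUE)
    v <- missingness_filter(rec(gt = gt, dp = dp), t)
    expect_identical(v$pass,
                     !(mean(is.na(gt)) > 0.2 || mean(dp < 2) > 0.2))
  }
})

test_that("MAF counts alleles over non-missing samples and folds", {
  expect_equal(compute_maf(c(rep(0L, 7), rep(1L, 3))), 0.15)
  expect_equal(compute_maf(rep(2L, 6)), 0)                  # folded
  expect_equal(compute_maf(c(1L, 1L, NA)), 0.5)             # NA excluded
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "missing")
  set.seed(2)
  g <- sample(0:2, 30, TRUE)
  expect_equal(compute_maf(g), compute_maf(2L - g))          # label swap
})

test_that("HWE chi-square matches the direct formula and conventions", {
  expect_equal(hwe_chisq(c(rep(0L, 25), rep(1L, 50), rep(2L, 25))), 1.0)
  expect_equal(hwe_chisq(rep(0L, 10)), 1.0)                 # monomorphic
  set.seed(3)
  for (i in 1:30) {
    g <- sample(0:2, 60, TRUE)
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    p <- (2 * obs[1] + obs[2]) / (2 * length(g))
    e <- length(g) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((obs - e)^2 / e)
    expect_equal(hwe_chisq(g), pchisq(stat, 1, lower.tail = FALSE))
  }
})

test_that("cohort filtering tallies planted hard-filter violations exactly", {
  st <- small_study()
  filt <- filter_cohort(st$vcf, genome = st$genome)
  planted <- sum(grepl("^clause_", st$truth$fate))
  expect_identical(unname(filt$tally["HARD_FILTER"]), planted)
  expect_identical(sum(filt$tally), planted)     # nothing else fires
  expect_identical(nrow(filt$snps), st$cfg$n_snps - planted)
  # survivors + first-failure tallies account for every input site
  expect_identical(nrow(filt$snps) + sum(filt$tally), filt$n_input)
  # survivors carry full flanks and folded MAF
  expect_true(all(nchar(filt$snps$flank_left) == 150))
  expect_true(all(filt$snps$maf >= 0 & filt$snps$maf <= 0.5))
})

test_that("disabling every filter keeps all biallelic SNPs", {
  st <- small_study()
  filt <- filter_cohort(st$vcf, genome = st$genome,
                        enable = c(hard = FALSE, depth = FALSE,
                                   missing = FALSE, maf = FALSE, hwe = FALSE))
  expect_identical(nrow(filt$snps), sum(st$vcf$sites$n_alt == 1L))
})

test_that("multi-allelic and indel records are tallied NOT_BIALLELIC", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t10\t.\tA\tG,T\t.\t.\tDP=100\tGT\t0/1",
    "chr1\t20\t.\tAT\tA\t.\t.\tDP=100\tGT\t0/1",
    "chr1\t30\t.\tC\tT\t.\t.\tDP=100\tGT\t0/1"
  ), p)
  filt <- filter_cohort(read_vcf(p), enable = c(missing = FALSE))
  expect_identical(unname(filt$tally["NOT_BIALLELIC"]), 2L)
  expect_identical(nrow(filt$snps), 1L)
})
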