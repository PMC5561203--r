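# construct an in-memory read table without touching SAM files
mk_reads <- function(contig, pos0, seq, qual = NULL, flag = 0L, mapq = 60L) {
  n <- length(seq)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40
  contig <- rep_len(contig, n); pos0 <- rep_len(pos0, n)
  flag <- rep_len(flag, n); mapq <- rep_len(mapq, n)
  mapped <- bitwAnd(flag, 4L) == 0L
  df <- data.frame(qname = sprintf("r%03d", seq_len(n)), flag = flag,
                   contig = ifelse(mapped, contig, NA), pos0 = ifelse(mapped, pos0, NA),
                   mapq = mapq, seq = seq, qual = rep_len(qual, n),
                   mapped = mapped, duplicate = bitwAnd(flag, 1024L) != 0L,
                   unique = mapped & mapq >= 30L, stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

test_that("read filtering applies the N, quality, adapter and duplicate rules", {
  seq50 <- strrep("ACGTA", 10)
  n6 <- paste0(strrep("N", 6), substr(seq50, 7, 50))      # 12% N
  n5 <- paste0(strrep("N", 5), substr(seq50, 6, 50))      # 10% N: boundary
  q20 <- paste0(strrep("+", 20), strrep("I", 30))         # 40% at Q10
  q21 <- paste0(strrep("+", 21), strrep("I", 29))         # 42% at Q10
  rd <- mk_reads("c1", 0L,
                 c(seq50, n6, n5, seq50, seq50, paste0("ACGT", "AGATCGGAAGAGC",
                                                       strrep("T", 33))),
                 qual = c(strrep("I", 50), strrep("I", 50), strrep("I", 50),
                          q20, q21, strrep("I", 50)),
                 flag = c(0L, 0L, 0L, 0L, 0L, 0L))
  res <- filter_reads(rd, adapter = "AGATCGGAAGAGC")
  expect_identical(unname(res$tally["N_FRACTION"]), 1L)   # only the 12% read
  expect_identical(unname(res$tally["LOW_QUALITY"]), 1L)  # only the 42% read
  expect_identical(unname(res$tally["ADAPTER"]), 1L)
  expect_identical(unname(res$tally["kept"]), 3L)
  # duplicates and missing qualities
  rd2 <- mk_reads("c1", 0L, c(seq50, seq50), qual = c(strrep("I", 50), "*"),
                  flag = c(1024L, 0L))
  res2 <- filter_reads(rd2)
  expect_identical(unname(res2$tally["DUPLICATE"]), 1L)
  expect_identical(unname(res2$tally["NO_QUALITY"]), 1L)
  expect_identical(nrow(res2$reads), 0L)
  res3 <- filter_reads(rd2, dedup = FALSE)
  expect_identical(unname(res3$tally["DUPLICATE"]), 0L)
})

test_that("base classification partitions aligned bases exactly", {
  g <- reference_genome(c(c1 = strrep("A", 10000)))
  tgt <- target_regions(data.frame(id = "t1", contig = "c1", pos0 = 5000L), g)
  expect_identical(tgt$start0, 4700L)
  expect_identical(tgt$end0, 5301L)
  rd <- mk_reads("c1", c(5000L, 4651L, 9000L, 0L, 300L),
                 rep(strrep("A", 50), 5),
                 flag = c(0L, 0L, 0L, 4L, 0L), mapq = c(60L, 60L, 10L, 0L, 60L))
  b <- classify_alignment_bases(rd, tgt)
  expect_identical(unname(b["total"]), 250)
  expect_identical(unname(b["aligned"]), 200)
  expect_identical(unname(b["unique"]), 150)          # MAPQ 10 not unique
  # read at 4651 overlaps the region by exactly 1 base -> fully credited
  expect_identical(unname(b["on_flank"]), 100)
  expect_identical(unname(b["off_target"]), 100)
  expect_identical(unname(b["aligned"]), unname(b["on_flank"] + b["off_target"]))
  # per-base mode credits only the intersecting base
  b2 <- classify_alignment_bases(rd, tgt, per_base = TRUE)
  expect_identical(unname(b2["on_flank"]), 51)
})

test_that("depth profile is zero without reads and flat under uniform tiling", {
  g <- reference_genome(c(c1 = strrep("ACGT", 2500)))
  tgt <- target_regions(data.frame(id = c("t1", "t2"), contig = "c1",
                                   pos0 = c(3000L, 7000L)), g)
  empty <- mk_reads("c1", integer(), character())
  prof0 <- depth_profile(empty, tgt, g)
  expect_identical(length(prof0$mean_depth), 601L)
  expect_true(all(prof0$mean_depth == 0))
  # perfect 2X tiling: reads at every 25 bp of a 10-kb contig
  starts <- seq(0L, 9950L, by = 25L)
  rd <- mk_reads("c1", starts, rep(strrep("A", 50), length(starts)))
  prof <- depth_profile(rd, tgt, g)
  expect_true(all(abs(prof$mean_depth - 2) <= 1))   # edge effects only
  expect_identical(unname(prof$snp_depth), c(2, 2))
})

test_that("overlapping targets are profiled independently", {
  g <- reference_genome(c(c1 = strrep("A", 2000)))
  tgt <- target_regions(data.frame(id = c("a", "b"), contig = "c1",
                                   pos0 = c(900L, 1000L)), g)
  rd <- mk_reads("c1", 875L, strrep("A", 50))   # covers 875..924
  prof <- depth_profile(rd, tgt, g)
  expect_identical(unname(prof$snp_depth), c(1, 0))
  expect_identical(prof$n_targets, rep(2L, 601L))
})

test_that("coverage uniformity fractions follow the direct recount", {
  u <- coverage_uniformity(c(0, 10, 10, 20))
  expect_equal(unname(u$fractions), c(0.75, 0.75))
  u2 <- coverage_uniformity(rep(7, 12))
  expect_equal(unname(u2$fractions), c(1, 1))
  expect_error(coverage_uniformity(rep(0, 5)), "zero mean")
  set.seed(91)
  d <- rexp(500, 1 / 30)
  u3 <- coverage_uniformity(d)
  expect_equal(unname(u3$fractions[1]), mean(d / mean(d) >= 0.4))
  expect_gte(u3$fractions[1], u3$fractions[2])   # monotone in threshold
})

test_that("GC-depth table groups regions into the configured bins", {
  set.seed(93)
  gc40 <- paste(sample(c(rep("G", 2), rep("C", 2), rep("A", 3), rep("T", 3)),
                       601, TRUE), collapse = "")
  gc60 <- paste(sample(c(rep("G", 3), rep("C", 3), rep("A", 2), rep("T", 2)),
                       601, TRUE), collapse = "")
  g <- reference_genome(c(c1 = paste0(gc40, strrep("A", 100), gc60)))
  tgt <- data.frame(id = c("a", "b"), contig = "c1", pos0 = c(300L, 1001L),
                    start0 = c(0L, 701L), end0 = c(601L, 1302L))
  tab <- gc_depth_table(tgt, g, c(10, 30))
  expect_identical(tab$n, c(0L, 1L, 1L, 0L))
  expect_equal(tab$mean_depth[2:3], c(10, 30))
  tab2 <- gc_depth_table(tgt[c(1, 1), ], g, c(5, 15))
  expect_identical(sum(tab2$n > 0), 1L)          # same GC: one occupied bin
})

test_that("SNP concordance counts shared sites by position and allele", {
  a <- data.frame(contig = "c1", pos0 = 1:10, alt = "G")
  expect_equal(snp_concordance(a, a)$frac_a, 1)
  b <- data.frame(contig = "c1", pos0 = 11:20, alt = "G")
  expect_equal(snp_concordance(a, b)$shared, 0)
  set.seed(95)
  shared <- data.frame(contig = "c1", pos0 = sample.int(1e6, 80), alt = "T")
  only_a <- data.frame(contig = "c1", pos0 = 1e6 + 1:20, alt = "T")
  only_b <- data.frame(contig = "c2", pos0 = 1:20, alt = "T")
  cc <- snp_concordance(rbind(shared, only_a), rbind(shared, only_b))
  expect_identical(cc$shared, 80L)
  expect_equal(cc$frac_a, 0.8)
  expect_equal(cc$frac_b, 0.8)
  # allele mismatch at the same position is not shared
  a2 <- data.frame(contig = "c1", pos0 = 5L, alt = "G")
  b2 <- data.frame(contig = "c1", pos0 = 5L, alt = "T")
  expect_identical(snp_concordance(a2, b2)$shared, 0L)
})
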