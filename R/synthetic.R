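# Deterministic synthetic fixtures: genomes with planted screen defects,
# cohort VCFs with planted filter violations, and capture reads placed by a
# Gaussian kernel around targets. Every generated record has a truth entry,
# so downstream tallies can be checked exactly.

#' Synthetic study configuration
#'
#' Defaults mirror the chip-design study conditions at desk scale: a
#' 73-individual design cohort, 150-bp screening flanks, 50-bp single-end
#' capture reads with 56% of reads placed on targets and a 75-bp placement
#' kernel (so coverage is negligible beyond ~200 bp from a target), 13% of
#' reads unaligned, and an average target depth near 40X via
#' `reads_per_target`. Genome and SNP counts are desk-scale.
#'
#' @param seed integer seed fixing every downstream byte.
#' @param contig_len length of the design contig (bp).
#' @param n_snps total SNP loci to place.
#' @param n_hairpin,n_dup,n_repeat,n_per_clause planted defect counts:
#'   hairpin-bearing flanks, flanks duplicated verbatim elsewhere, SNPs
#'   inside a repeat annotation, and sites violating each of the five
#'   hard-filter clauses (QD, FS, MQ, MQRankSum, ReadPosRankSum).
#' @param n_individuals cohort size.
#' @param maf_range true MAFs are drawn uniformly from this range.
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean mean of the per-sample Poisson depth.
#' @param stem_len,loop_len planted hairpin geometry (stem 10 > the 8-bp
#'   limit, loop 4).
#' @param read_len read length (bp, single-end).
#' @param reads_per_target mean on-target reads per target SNP; sets the
#'   total read count as `reads_per_target * n_targets / on_target_frac`.
#'   At the default kernel a read covers its target's SNP base with
#'   probability ~0.26, so 153 reads/target gives about 40X there.
#' @param on_target_frac fraction of all reads placed on targets.
#' @param unmapped_frac fraction of all reads emitted unmapped.
#' @param kernel_sd s.d. (bp) of the Gaussian placement kernel around the
#'   target SNP.
#' @param dup_rate,n_read_rate,lowq_rate planted rates of PCR-duplicate,
#'   N-rich (16% N) and low-quality (50% of bases at Q5) reads.
#' @param lowmapq_frac fraction of mapped reads emitted with MAPQ 0
#'   (non-unique alignments).
#' @param base_quality Phred quality of ordinary bases.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20260101L,
                             contig_len = 400000L, n_snps = 200L,
                             n_hairpin = 30L, n_dup = 20L, n_repeat = 10L,
                             n_per_clause = 10L,
                             n_individuals = 73L,
                             maf_range = c(0.05, 0.5),
                             missing_rate = 0.05, depth_mean = 8,
                             stem_len = 10L, loop_len = 4L,
                             read_len = 50L, reads_per_target = 153L,
                             on_target_frac = 0.56, unmapped_frac = 0.13,
                             kernel_sd = 75, dup_rate = 0.02,
                             n_read_rate = 0.01, lowq_rate = 0.01,
                             lowmapq_frac = 0.10, base_quality = 35L) {
  cfg <- as.list(environment())
  stopifnot(cfg$on_target_frac + cfg$unmapped_frac <= 1,
            cfg$n_hairpin + cfg$n_dup + cfg$n_repeat +
              5L * cfg$n_per_clause <= cfg$n_snps)
  class(cfg) <- "synthetic_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

HARD_CLAUSES <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Generate a synthetic genome with planted screen defects
#'
#' Builds an i.i.d. uniform-composition design contig, places `n_snps` SNP
#' loci at jittered regular spacing, and rejection-samples each locus
#' neighbourhood until both 150-bp flanks are free of incidental hairpins,
#' so that the screen truth is exact. Then plants, per assigned fate:
#' a random stem-loop (stem `stem_len`) in the left flank; a verbatim copy
#' of the locus neighbourhood on a duplication-bank contig (copies recorded
#' in the repeat annotation, sources left clean so they trip the uniqueness
#' screen, not the repeat screen); or a repeat interval over the SNP itself.
#' Hard-filter clause fates carry no genome-side plant.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (a `reference_genome`), `repeats` (an
#'   `interval_set`), and `truth` (data.frame: `id`, `contig`, `pos0`,
#'   `true_maf`, `fate` in clean / hairpin / dup / repeat / clause_<KEY>).
#' @export
make_genome <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_snps
  L <- config$contig_len
  spacing <- L %/% (n + 1L)
  if (spacing < 700L) stop("contig too short to place non-overlapping flanks")
  pos0 <- as.integer(seq_len(n) * spacing +
                       round(runif(n, -spacing / 4, spacing / 4)))
  fates <- c(rep("hairpin", config$n_hairpin), rep("dup", config$n_dup),
             rep("repeat", config$n_repeat),
             rep(paste0("clause_", HARD_CLAUSES),
                 each = config$n_per_clause))
  fates <- c(fates, rep("clean", n - length(fates)))
  fates <- sample(fates)
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # rejection-sample each locus neighbourhood until both flanks screen clean
  flank <- 150L
  for (i in seq_len(n)) {
    p <- pos0[i]
    repeat {
      left <- paste(chars[(p - flank + 1L):p], collapse = "")
      right <- paste(chars[(p + 2L):(p + 1L + flank)], collapse = "")
      if (is.null(detect_hairpin(left)) && is.null(detect_hairpin(right)))
        break
      win <- (p - flank):(p + 1L + flank)
      chars[win] <- sample(c("A", "C", "G", "T"), length(win), replace = TRUE)
    }
  }

  # plant hairpins: random stem + loop + reverse-complement stem in the left
  # flank, ending 20 bp before the SNP
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in which(fates == "hairpin")) {
    p <- pos0[i]
    stem <- sample(c("A", "C", "G", "T"), config$stem_len, replace = TRUE)
    loop <- sample(c("A", "C", "G", "T"), config$loop_len, replace = TRUE)
    unit <- c(stem, loop, rev(unname(comp[stem])))
    at <- p - 20L - length(unit)  # 0-based insert start
    chars[(at + 1L):(at + length(unit))] <- unit
  }

  seq1 <- paste(chars, collapse = "")

  # duplication bank: verbatim copies of [pos-150, pos+151), N-separated
  rep_contig <- character()
  rep_start <- rep_end <- integer()
  dup_idx <- which(fates == "dup")
  sequences <- c(chr1 = seq1)
  if (length(dup_idx)) {
    pieces <- character()
    cursor <- 0L
    sep <- strrep("N", 50L)
    for (i in dup_idx) {
      p <- pos0[i]
      piece <- substr(seq1, p - flank + 1L, p + flank + 1L)  # 301 bp
      pieces <- c(pieces, piece, sep)
      rep_contig <- c(rep_contig, "dupbank")
      rep_start <- c(rep_start, cursor)
      rep_end <- c(rep_end, cursor + nchar(piece))
      cursor <- cursor + nchar(piece) + 50L
    }
    sequences <- c(sequences, dupbank = paste(pieces, collapse = ""))
  }
  # repeat annotations over the repeat-fate SNPs themselves
  for (i in which(fates == "repeat")) {
    rep_contig <- c(rep_contig, "chr1")
    rep_start <- c(rep_start, pos0[i] - 5L)
    rep_end <- c(rep_end, pos0[i] + 6L)
  }
  truth <- data.frame(
    id = sprintf("snp%04d", seq_len(n)),
    contig = "chr1", pos0 = pos0,
    true_maf = runif(n, config$maf_range[1], config$maf_range[2]),
    fate = fates, stringsAsFactors = FALSE
  )
  list(genome = reference_genome(sequences),
       repeats = interval_set(rep_contig, rep_start, rep_end),
       truth = truth)
}

#' Generate a synthetic cohort VCF with planted filter violations
#'
#' Genotypes are drawn binomially from each SNP's true MAF under HWE, with
#' independent per-genotype missingness; per-sample depths are Poisson.
#' INFO metrics are drawn from comfortably passing ranges except at sites
#' whose truth fate is `clause_<KEY>`, where that key alone is planted in
#' its violating range.
#'
#' @param genome a `reference_genome` (supplies REF alleles).
#' @param truth truth table from [make_genome()].
#' @param config a [synthetic_config()].
#' @return a `cohort_vcf` (see [read_vcf()]).
#' @export
make_cohort_vcf <- function(genome, truth, config = synthetic_config()) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  ns <- config$n_individuals
  gt <- matrix(rbinom(n * ns, 2L, rep(truth$true_maf, ns)), nrow = n)
  gt[matrix(runif(n * ns) < config$missing_rate, nrow = n)] <- NA_integer_
  depth <- matrix(rpois(n * ns, config$depth_mean), nrow = n)
  samples <- sprintf("ind%03d", seq_len(ns))
  colnames(gt) <- colnames(depth) <- samples

  ref <- vapply(seq_len(n), function(i)
    genome_subseq(genome, truth$contig[i], truth$pos0[i], truth$pos0[i] + 1L),
    character(1))
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  pass <- list(QD = c(20, 30), FS = c(0, 10), MQ = c(50, 60),
               MQRankSum = c(-2, 2), ReadPosRankSum = c(-2, 2))
  fail <- list(QD = c(0.2, 1.9), FS = c(61, 120), MQ = c(10, 39),
               MQRankSum = c(-25, -12.6), ReadPosRankSum = c(-15, -8.1))
  sites <- data.frame(contig = truth$contig, pos1 = truth$pos0 + 1L,
                      pos0 = truth$pos0, id = truth$id, ref = ref, alt = alt,
                      n_alt = 1L, stringsAsFactors = FALSE)
  for (k in HARD_CLAUSES) {
    v <- runif(n, pass[[k]][1], pass[[k]][2])
    planted <- truth$fate == paste0("clause_", k)
    v[planted] <- runif(sum(planted), fail[[k]][1], fail[[k]][2])
    sites[[k]] <- round(v, 2)
  }
  sites$DP <- rowSums(depth)
  sites$HaplotypeScore <- NA_real_
  structure(list(sites = sites, gt = gt, depth = depth, samples = samples),
            class = "cohort_vcf")
}

int_to_qual <- function(q) intToUtf8(q + 33L, multiple = FALSE)

#' Generate synthetic capture reads around target SNPs
#'
#' On-target reads are centered on a uniformly chosen target SNP plus
#' Gaussian jitter (`kernel_sd`); background reads are uniform over the
#' genome; a configured fraction is emitted unmapped with random sequence.
#' Planted defects: PCR duplicates (copies of existing mapped reads with the
#' 0x400 flag), N-rich reads and low-quality reads at their configured
#' rates, and MAPQ-0 alignments for the non-unique fraction.
#'
#' @param genome a `reference_genome`.
#' @param targets data.frame with `id`, `contig`, `pos0`.
#' @param config a [synthetic_config()].
#' @param n_reads total primary reads; default
#'   `reads_per_target * nrow(targets) / on_target_frac`.
#' @return list with `reads` (a `read_set`) and `truth` (data.frame:
#'   `qname`, `origin` = target id / "background" / "unmapped", logicals
#'   `planted_dup`, `planted_n`, `planted_lowq`).
#' @export
make_capture_reads <- function(genome, targets, config = synthetic_config(),
                               n_reads = NULL) {
  set.seed(config$seed + 2L)
  if (nrow(targets) == 0L) stop("no targets")
  if (is.null(n_reads))
    n_reads <- as.integer(round(config$reads_per_target * nrow(targets) /
                                  config$on_target_frac))
  rl <- config$read_len
  n_on <- round(config$on_target_frac * n_reads)
  n_un <- round(config$unmapped_frac * n_reads)
  n_bg <- n_reads - n_on - n_un

  # on-target placements
  ti <- sample.int(nrow(targets), n_on, replace = TRUE)
  centers <- targets$pos0[ti] + round(rnorm(n_on, 0, config$kernel_sd))
  on <- data.frame(contig = targets$contig[ti],
                   pos0 = centers - rl %/% 2L,
                   origin = targets$id[ti], stringsAsFactors = FALSE)
  # background placements, uniform over contigs by length
  clens <- genome$lengths
  bc <- sample(names(clens), n_bg, replace = TRUE, prob = clens)
  bp <- floor(runif(n_bg) * (clens[bc] - rl))
  bg <- data.frame(contig = bc, pos0 = as.integer(bp),
                   origin = "background", stringsAsFactors = FALSE)
  mapped <- rbind(on, bg)
  mapped$pos0 <- pmax(0L, pmin(mapped$pos0,
                               as.integer(clens[mapped$contig]) - rl))
  mapped$seq <- vapply(seq_len(nrow(mapped)), function(i)
    genome_subseq(genome, mapped$contig[i], mapped$pos0[i],
                  mapped$pos0[i] + rl), character(1))
  mapped$flag <- 0L
  mapped$mapq <- ifelse(runif(nrow(mapped)) < config$lowmapq_frac, 0L, 60L)

  unmapped <- data.frame(contig = rep(NA_character_, n_un),
                         pos0 = rep(NA_integer_, n_un),
                         origin = rep("unmapped", n_un),
                         seq = vapply(integer(n_un),
                                      function(z) random_dna(rl), character(1)),
                         flag = rep(4L, n_un), mapq = rep(0L, n_un),
                         stringsAsFactors = FALSE)
  reads <- rbind(mapped, unmapped)
  nr <- nrow(reads)
  qual <- strrep(intToUtf8(config$base_quality + 33L), rl)
  reads$qual <- qual

  planted_n <- runif(nr) < config$n_read_rate
  for (i in which(planted_n)) {
    pos <- sample.int(rl, ceiling(0.16 * rl))
    s <- strsplit(reads$seq[i], "")[[1]]
    s[pos] <- "N"
    reads$seq[i] <- paste(s, collapse = "")
  }
  lowq <- strrep(intToUtf8(5L + 33L), rl %/% 2L)
  planted_lowq <- !planted_n & runif(nr) < config$lowq_rate
  reads$qual[planted_lowq] <- paste0(lowq, strrep(intToUtf8(config$base_quality + 33L),
                                                  rl - rl %/% 2L))
  # PCR duplicates: copies of existing mapped reads, flagged 0x400
  n_dup <- round(config$dup_rate * nr)
  dup_src <- sample(which(reads$flag == 0L), n_dup, replace = TRUE)
  dups <- reads[dup_src, , drop = FALSE]
  dups$flag <- bitwOr(dups$flag, 1024L)
  planted_dup <- c(rep(FALSE, nr), rep(TRUE, n_dup))
  reads <- rbind(reads, dups)
  planted_n <- c(planted_n, rep(FALSE, n_dup))
  planted_lowq <- c(planted_lowq, rep(FALSE, n_dup))

  reads$qname <- sprintf("read%06d", seq_len(nrow(reads)))
  reads$mapped <- bitwAnd(reads$flag, 4L) == 0L
  reads$duplicate <- bitwAnd(reads$flag, 1024L) != 0L
  reads$unique <- reads$mapped & reads$mapq >= 30L
  truth <- data.frame(qname = reads$qname, origin = reads$origin,
                      planted_dup = planted_dup, planted_n = planted_n,
                      planted_lowq = planted_lowq, stringsAsFactors = FALSE)
  reads <- reads[, c("qname", "flag", "contig", "pos0", "mapq", "seq",
                     "qual", "mapped", "duplicate", "unique")]
  class(reads) <- c("read_set", "data.frame")
  rownames(reads) <- NULL
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Write a complete synthetic study to a directory
#'
#' Emits `genome.fa`, `repeats.bed`, `cohort.vcf`, `targets.bed`,
#' `reads.sam` and `truth_snps.tsv` / `truth_reads.tsv`. Reads are
#' simulated over all SNP loci as targets (the pipeline re-derives its own
#' target list).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_synthetic_study <- function(config = synthetic_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- make_genome(config)
  vcf <- make_cohort_vcf(g$genome, g$truth, config)
  reads <- make_capture_reads(g$genome, g$truth, config)
  write_fasta(g$genome, file.path(dir, "genome.fa"))
  if (nrow(g$repeats)) write_bed(g$repeats, file.path(dir, "repeats.bed"))
  else file.create(file.path(dir, "repeats.bed"))
  write_vcf(vcf, file.path(dir, "cohort.vcf"))
  write_bed(interval_set(g$truth$contig, g$truth$pos0, g$truth$pos0 + 1L),
            file.path(dir, "targets.bed"), names = g$truth$id)
  write_sam(reads$reads, g$genome, file.path(dir, "reads.sam"))
  write.table(g$truth, file.path(dir, "truth_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(reads$truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genome = g$genome, repeats = g$repeats, truth = g$truth,
                 vcf = vcf, reads = reads))
}
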