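# Cohort SNP filtering: GATK-style hard-filter expression, site depth range,
# missingness / low-depth sample rules, and generic MAF / HWE screens.

#' Filter thresholds for cohort SNP selection
#'
#' Defaults reproduce the design-cohort criteria: the hard-filter expression
#' `QD < 2.0 || FS > 60.0 || MQ < 40.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0` (a site fails if ANY present key triggers; absent
#' keys never trigger, matching GATK VariantFiltration semantics), total site
#' depth inside \[80, 1000\] inclusive, missing-genotype rate at most 20%, and
#' at most 20% of individuals below depth 2. The GWA-side variant filter is
#' expressed by overriding thresholds (e.g. `qd_min = 4`,
#' `haplotypescore_max = 13`).
#'
#' @param qd_min fail when QD below this (strict).
#' @param fs_max fail when FS above this (strict).
#' @param mq_min fail when MQ below this (strict).
#' @param mqranksum_min fail when MQRankSum below this (strict).
#' @param readposranksum_min fail when ReadPosRankSum below this (strict).
#' @param haplotypescore_max fail when HaplotypeScore above this (strict);
#'   `NA` disables the clause (design-cohort default).
#' @param site_depth_range inclusive total-depth bounds.
#' @param max_missing_rate exclude when missing fraction strictly exceeds this.
#' @param low_depth_cutoff an individual counts as low-depth when its depth is
#'   strictly below this.
#' @param max_lowdepth_fraction exclude when the low-depth fraction strictly
#'   exceeds this.
#' @param missingness_mode `"any"` (either trigger alone excludes; default) or
#'   `"both"` (literal conjunction: both must trigger).
#' @param maf_min exclude when folded MAF is strictly below this; 0 disables.
#' @param hwe_p_min exclude when the HWE chi-square p-value is strictly below
#'   this; 0 disables.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                              mqranksum_min = -12.5, readposranksum_min = -8.0,
                              haplotypescore_max = NA_real_,
                              site_depth_range = c(80, 1000),
                              max_missing_rate = 0.20,
                              low_depth_cutoff = 2,
                              max_lowdepth_fraction = 0.20,
                              missingness_mode = c("any", "both"),
                              maf_min = 0, hwe_p_min = 0) {
  missingness_mode <- match.arg(missingness_mode)
  stopifnot(length(site_depth_range) == 2,
            site_depth_range[1] <= site_depth_range[2])
  structure(list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 mqranksum_min = mqranksum_min,
                 readposranksum_min = readposranksum_min,
                 haplotypescore_max = haplotypescore_max,
                 site_depth_range = site_depth_range,
                 max_missing_rate = max_missing_rate,
                 low_depth_cutoff = low_depth_cutoff,
                 max_lowdepth_fraction = max_lowdepth_fraction,
                 missingness_mode = missingness_mode,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "filter_thresholds")
}

verdict <- function(reasons = character()) {
  list(pass = length(reasons) == 0L, reasons = reasons)
}

info_val <- function(record, key) {
  if (!key %in% names(record$info)) return(NA_real_)
  record$info[[key]]
}

#' Hard-filter a variant record
#'
#' Evaluates the OR-expression of site annotations. A clause only triggers
#' when its key is present; all comparisons are strict, so boundary values
#' (QD = 2.0, FS = 60.0, MQ = 40.0, ...) pass.
#'
#' @param record a `variant_record`.
#' @param t a [filter_thresholds()].
#' @return list with `pass` and `reasons` (empty iff pass).
#' @export
apply_hard_filter <- function(record, t = filter_thresholds()) {
  qd <- info_val(record, "QD"); fs <- info_val(record, "FS")
  mq <- info_val(record, "MQ"); mqrs <- info_val(record, "MQRankSum")
  rprs <- info_val(record, "ReadPosRankSum")
  hs <- info_val(record, "HaplotypeScore")
  fail <- isTRUE(qd < t$qd_min) || isTRUE(fs > t$fs_max) ||
    isTRUE(mq < t$mq_min) || isTRUE(mqrs < t$mqranksum_min) ||
    isTRUE(rprs < t$readposranksum_min) ||
    (!is.na(t$haplotypescore_max) && isTRUE(hs > t$haplotypescore_max))
  verdict(if (fail) "HARD_FILTER" else character())
}

#' Site total-depth filter
#'
#' Total depth is INFO/DP when present, otherwise the sum of per-sample
#' depths. Bounds are inclusive: DP = 80 and DP = 1000 pass.
#'
#' @inheritParams apply_hard_filter
#' @return list with `pass` and `reasons`; an undeterminable depth fails with
#'   reason `DEPTH_RANGE_UNKNOWN`.
#' @export
site_depth_filter <- function(record, t = filter_thresholds()) {
  dp <- info_val(record, "DP")
  if (is.na(dp)) {
    sd <- record$sample_depths
    if (length(sd) == 0L || all(is.na(sd)))
      return(verdict("DEPTH_RANGE_UNKNOWN"))
    dp <- sum(sd, na.rm = TRUE)
  }
  ok <- dp >= t$site_depth_range[1] && dp <= t$site_depth_range[2]
  verdict(if (ok) character() else "DEPTH_RANGE")
}

#' Missingness and low-depth-sample filter
#'
#' Two triggers: missing-genotype fraction strictly above
#' `max_missing_rate`, and fraction of individuals with depth below
#' `low_depth_cutoff` strictly above `max_lowdepth_fraction`. Under
#' `missingness_mode = "any"` (default) either trigger alone excludes the
#' site; under `"both"` the site is excluded only when both trigger.
#'
#' @inheritParams apply_hard_filter
#' @export
missingness_filter <- function(record, t = filter_thresholds()) {
  n <- length(record$genotypes)
  stopifnot(n >= 1L)
  miss_frac <- mean(is.na(record$genotypes))
  lowdep_frac <- mean(!is.na(record$sample_depths) &
                        record$sample_depths < t$low_depth_cutoff)
  m <- miss_frac > t$max_missing_rate
  l <- lowdep_frac > t$max_lowdepth_fraction
  reasons <- character()
  if (t$missingness_mode == "any") {
    if (m) reasons <- c(reasons, "MISSINGNESS")
    if (l) reasons <- c(reasons, "LOW_DEPTH_SAMPLES")
  } else if (m && l) {
    reasons <- c("MISSINGNESS", "LOW_DEPTH_SAMPLES")
  }
  verdict(reasons)
}

#' Folded minor allele frequency
#'
#' Alt-allele count over twice the number of non-missing genotypes, folded to
#' `min(f, 1 - f)`. Missing genotypes are excluded from the denominator.
#'
#' @param genotypes integer alt dosages (0/1/2, `NA` missing).
#' @return frequency in \[0, 0.5\].
#' @export
compute_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L) stop("all genotypes missing")
  alt <- sum(g)
  tot <- 2L * length(g)
  min(alt, tot - alt) / tot     # integer fold: exactly label-swap invariant
}

#' Hardy-Weinberg equilibrium chi-square p-value
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' expectations p^2 / 2pq / q^2 at the sample allele frequency, without
#' continuity correction. Monomorphic sites return p = 1 by convention.
#'
#' @param genotypes integer alt dosages (0/1/2, `NA` missing).
#' @return p-value in \[0, 1\].
#' @export
hwe_chisq <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) < 2L) stop("need at least 2 non-missing genotypes")
  n <- length(g)
  obs <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1.0)
  expd <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

FILTER_PRIORITY <- c("NOT_BIALLELIC", "HARD_FILTER", "DEPTH_RANGE",
                     "DEPTH_RANGE_UNKNOWN", "MISSINGNESS",
                     "LOW_DEPTH_SAMPLES", "MAF", "HWE")

site_reasons <- function(record, t, enabled) {
  reasons <- character()
  if (length(record$alt) != 1L || nchar(record$ref) != 1L ||
      nchar(record$alt[1]) != 1L)
    reasons <- c(reasons, "NOT_BIALLELIC")
  if (enabled["hard"]) {
    v <- apply_hard_filter(record, t); reasons <- c(reasons, v$reasons)
  }
  if (enabled["depth"]) {
    v <- site_depth_filter(record, t); reasons <- c(reasons, v$reasons)
  }
  if (enabled["missing"]) {
    v <- missingness_filter(record, t); reasons <- c(reasons, v$reasons)
  }
  biallelic_snp <- !("NOT_BIALLELIC" %in% reasons)
  if (biallelic_snp && any(!is.na(record$genotypes))) {
    maf <- compute_maf(record$genotypes)
    if (enabled["maf"] && t$maf_min > 0 && maf < t$maf_min)
      reasons <- c(reasons, "MAF")
    if (enabled["hwe"] && t$hwe_p_min > 0 &&
        sum(!is.na(record$genotypes)) >= 2L &&
        hwe_chisq(record$genotypes) < t$hwe_p_min)
      reasons <- c(reasons, "HWE")
  }
  unique(reasons)
}

#' Filter a cohort VCF down to candidate SNPs
#'
#' Applies the enabled filters to every site and keeps biallelic
#' single-nucleotide variants passing all of them. Survivors carry folded MAF
#' and 150-bp flanks (when a genome is supplied). The rejection tally assigns
#' each failed site its highest-priority reason (priority:
#' NOT_BIALLELIC, HARD_FILTER, DEPTH_RANGE, MISSINGNESS, LOW_DEPTH_SAMPLES,
#' MAF, HWE), so survivors + tally total = input sites.
#'
#' @param vcf a `cohort_vcf` from [read_vcf()].
#' @param t a [filter_thresholds()].
#' @param genome optional `reference_genome` for flank extraction.
#' @param flank flank length in bp (default 150).
#' @param enable named logical vector switching individual filters off (names
#'   among `hard`, `depth`, `missing`, `maf`, `hwe`); all on by default.
#' @return list of class `candidate_set` with `snps` (data.frame: `id`,
#'   `contig`, `pos0`, `pos1`, `ref`, `alt`, `maf`, `flank_left`,
#'   `flank_right`, `flank_ok`), `tally` (named integer by first-failure
#'   reason), `n_input`, and `gt` (genotype matrix of survivors).
#' @export
filter_cohort <- function(vcf, t = filter_thresholds(), genome = NULL,
                          flank = 150L, enable = NULL) {
  enabled <- c(hard = TRUE, depth = TRUE, missing = TRUE, maf = TRUE,
               hwe = TRUE)
  if (!is.null(enable)) enabled[names(enable)] <- enable
  n <- nrow(vcf$sites)
  first_reason <- character(n)
  for (i in seq_len(n)) {
    r <- site_reasons(vcf_record(vcf, i), t, enabled)
    first_reason[i] <- if (length(r) == 0L) NA_character_ else
      r[which.min(match(r, FILTER_PRIORITY))]
  }
  keep <- is.na(first_reason)
  tally <- table(factor(first_reason[!keep], levels = FILTER_PRIORITY))
  sites <- vcf$sites[keep, , drop = FALSE]
  gt <- vcf$gt[keep, , drop = FALSE]
  maf <- if (nrow(gt)) apply(gt, 1, compute_maf) else numeric()
  snps <- data.frame(
    id = ifelse(is.na(sites$id) | sites$id == ".",
                paste0(sites$contig, ":", sites$pos1), sites$id),
    contig = sites$contig, pos0 = sites$pos0, pos1 = sites$pos1,
    ref = sites$ref, alt = sites$alt, maf = maf,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome) && nrow(snps)) {
    fl <- extract_flanks(genome, snps$contig, snps$pos0, flank = flank)
    snps$flank_left <- fl$left
    snps$flank_right <- fl$right
    snps$flank_ok <- fl$ok
  } else if (nrow(snps)) {
    snps$flank_left <- NA_character_
    snps$flank_right <- NA_character_
    snps$flank_ok <- NA
  }
  rownames(snps) <- NULL
  structure(list(snps = snps, tally = c(tally), n_input = n, gt = gt),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x$snps), "of", x$n_input, "sites kept\n")
  rej <- x$tally[x$tally > 0]
  if (length(rej)) {
    cat("rejections:\n")
    for (k in names(rej)) cat(sprintf("  %-18s %d\n", k, rej[[k]]))
  }
  invisible(x)
}
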