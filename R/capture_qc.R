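# Capture-evaluation metrics: read filtering, on/off-target base accounting,
# per-target depth profiles, coverage uniformity, GC-depth relation, and
# cross-platform SNP concordance.

#' Filter raw reads
#'
#' A read is dropped when (1) more than `max_n_frac` of its bases are N,
#' (2) more than `lowq_frac` of its bases have quality at or below
#' `lowq_cutoff`, (3) it contains the adapter sequence, or (4) its duplicate
#' flag is set (when `dedup`). Qualities are Phred+33; reads without
#' qualities (`*`) are dropped with their own reason.
#'
#' @param reads a `read_set` from [read_sam()].
#' @param max_n_frac maximum tolerated N fraction (strict: exactly 10% passes).
#' @param lowq_frac maximum tolerated low-quality fraction (strict).
#' @param lowq_cutoff quality value at or below which a base is low-quality.
#' @param adapter adapter sequence to match as a substring; `NULL` disables.
#' @param dedup drop flagged duplicates.
#' @return list with `reads` (kept subset), `tally` (named integer:
#'   `kept`, `N_FRACTION`, `LOW_QUALITY`, `ADAPTER`, `DUPLICATE`,
#'   `NO_QUALITY`). Each dropped read is tallied once, in that reason order.
#' @export
filter_reads <- function(reads, max_n_frac = 0.10, lowq_frac = 0.40,
                         lowq_cutoff = 10L, adapter = NULL, dedup = TRUE) {
  n <- nrow(reads)
  len <- nchar(reads$seq)
  n_frac <- vapply(gregexpr("N", reads$seq, fixed = TRUE), function(m)
    sum(m > 0L), numeric(1)) / len
  no_qual <- reads$qual == "*"
  lq_frac <- rep(0, n)
  for (i in which(!no_qual)) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    lq_frac[i] <- mean(q <= lowq_cutoff)
  }
  reason <- rep(NA_character_, n)
  if (dedup) reason[is.na(reason) & reads$duplicate] <- "DUPLICATE"
  if (!is.null(adapter))
    reason[is.na(reason) & grepl(adapter, reads$seq, fixed = TRUE)] <- "ADAPTER"
  reason[is.na(reason) & no_qual] <- "NO_QUALITY"
  reason[is.na(reason) & n_frac > max_n_frac] <- "N_FRACTION"
  reason[is.na(reason) & !no_qual & lq_frac > lowq_frac] <- "LOW_QUALITY"
  keep <- is.na(reason)
  tally <- c(kept = sum(keep),
             table(factor(reason[!keep],
                          levels = c("DUPLICATE", "ADAPTER", "NO_QUALITY",
                                     "N_FRACTION", "LOW_QUALITY"))))
  list(reads = reads[keep, , drop = FALSE], tally = tally)
}

#' Capture-target regions around SNPs
#'
#' Each target SNP defines a region of `flank` bp on either side (601 bp at
#' the default 300), clipped at contig edges.
#'
#' @param snps data.frame with `id`, `contig`, `pos0`.
#' @param genome a `reference_genome`.
#' @param flank flank extent in bp.
#' @return data.frame with `id`, `contig`, `pos0`, `start0`, `end0`.
#' @export
target_regions <- function(snps, genome, flank = 300L) {
  clen <- genome$lengths[snps$contig]
  data.frame(id = snps$id, contig = snps$contig, pos0 = snps$pos0,
             start0 = pmax(0L, snps$pos0 - flank),
             end0 = as.integer(pmin(clen, snps$pos0 + flank + 1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition aligned bases into on-flank and off-target
#'
#' By default a mapped read overlapping any target region by at least one
#' base credits ALL its bases on-flank (read-level classification, matching
#' megabase-by-read-class capture accounting); `per_base = TRUE` instead
#' counts only the intersecting bases as on-flank. Unmapped reads contribute
#' only to the total.
#'
#' @param reads a `read_set`.
#' @param targets data.frame from [target_regions()].
#' @param per_base use per-base intersection instead of read-level credit.
#' @return named numeric vector: `total`, `aligned`, `unique`, `on_flank`,
#'   `off_target` (base counts; `aligned = on_flank + off_target`).
#' @export
classify_alignment_bases <- function(reads, targets, per_base = FALSE) {
  len <- nchar(reads$seq)
  total <- sum(len)
  m <- reads$mapped
  aligned <- sum(len[m])
  uniq <- sum(len[m & reads$unique])
  tgt <- interval_set(targets$contig, targets$start0, targets$end0)
  tgt <- interval_merge(tgt)
  on_flank <- 0
  if (any(m)) {
    if (!per_base) {
      ov <- interval_overlaps_range(tgt, reads$contig[m], reads$pos0[m],
                                    reads$pos0[m] + len[m])
      on_flank <- sum(len[m][ov])
    } else {
      # targets are merged (disjoint), so summing per-hit intersection
      # widths never double-counts a read base
      g <- GenomicRanges::GRanges(reads$contig[m],
                                  IRanges::IRanges(reads$pos0[m] + 1L,
                                                   reads$pos0[m] + len[m]))
      tg <- as_granges(tgt)
      hits <- GenomicRanges::findOverlaps(g, tg)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- pmin(GenomicRanges::end(g)[qh], GenomicRanges::end(tg)[sh]) -
        pmax(GenomicRanges::start(g)[qh], GenomicRanges::start(tg)[sh]) + 1L
      on_flank <- sum(w)
    }
  }
  c(total = as.numeric(total), aligned = as.numeric(aligned),
    unique = as.numeric(uniq), on_flank = as.numeric(on_flank),
    off_target = as.numeric(aligned - on_flank))
}

# per-contig per-base depth from mapped, non-duplicate reads
depth_vectors <- function(reads, genome, exclude_duplicates = TRUE) {
  use <- reads$mapped
  if (exclude_duplicates) use <- use & !reads$duplicate
  r <- reads[use, , drop = FALSE]
  len <- nchar(r$seq)
  # difference-array accumulation: +1 at read start, -1 one past read end
  out <- lapply(names(genome$lengths), function(ct) {
    L <- genome$lengths[[ct]]
    sel <- r$contig == ct
    if (!any(sel)) return(integer(L))
    s <- pmax(0L, r$pos0[sel]) + 1L                 # 1-based clip
    e <- pmin(L, r$pos0[sel] + len[sel])
    ok <- s <= L & e >= s
    d <- tabulate(s[ok], nbins = L + 1L) - tabulate(e[ok] + 1L, nbins = L + 1L)
    cumsum(d)[seq_len(L)]
  })
  setNames(out, names(genome$lengths))
}

#' Base-by-base mean depth profile around target SNPs
#'
#' For each offset in `-flank..+flank`, the mean sequencing depth at
#' `pos0 + offset` across targets (overlapping targets count independently;
#' offsets falling outside a contig do not contribute for that target).
#' Duplicate-flagged reads are excluded.
#'
#' @param reads a `read_set`.
#' @param targets data.frame from [target_regions()].
#' @param genome a `reference_genome`.
#' @param flank profile half-width in bp.
#' @return list of class `depth_profile`: `offset` (-flank..flank),
#'   `mean_depth`, `n_targets` contributing per offset, and
#'   `snp_depth` (depth at offset 0 per target, named by target id).
#' @export
depth_profile <- function(reads, targets, genome, flank = 300L) {
  cov <- depth_vectors(reads, genome)
  offs <- seq.int(-flank, flank)
  sums <- numeric(length(offs))
  cnts <- integer(length(offs))
  snp_depth <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    ct <- targets$contig[i]
    L <- genome$lengths[[ct]]
    p <- targets$pos0[i] + offs        # 0-based positions
    inside <- p >= 0L & p < L
    sums[inside] <- sums[inside] + cov[[ct]][p[inside] + 1L]
    cnts <- cnts + inside
    snp_depth[i] <- if (targets$pos0[i] < L) cov[[ct]][targets$pos0[i] + 1L] else NA_real_
  }
  structure(list(offset = offs,
                 mean_depth = ifelse(cnts > 0L, sums / cnts, 0),
                 n_targets = cnts,
                 snp_depth = setNames(snp_depth, targets$id)),
            class = "depth_profile")
}

#' Coverage uniformity across targets
#'
#' Normalizes each target's depth by the mean across targets and reports the
#' fraction of targets at or above each threshold of the mean (defaults 0.4x
#' and 0.8x) plus deciles of the normalized distribution.
#'
#' @param per_target_depth numeric vector of per-target depths.
#' @param thresholds fractions of the mean to report.
#' @return list with `mean_depth`, `fractions` (named by threshold),
#'   `deciles`, `normalized`.
#' @export
coverage_uniformity <- function(per_target_depth,
                                thresholds = c(0.4, 0.8)) {
  stopifnot(length(per_target_depth) >= 1L)
  m <- mean(per_target_depth)
  if (m == 0) stop("zero mean depth")
  norm <- per_target_depth / m
  fr <- vapply(thresholds, function(t) mean(norm >= t), numeric(1))
  list(mean_depth = m,
       fractions = setNames(fr, paste0("frac_ge_", thresholds, "x")),
       deciles = stats::quantile(norm, probs = seq(0, 1, 0.1)),
       normalized = norm)
}

#' GC-content versus depth table
#'
#' Computes each target region's GC fraction from the genome, groups regions
#' into GC bins, and reports per-bin mean depth and region count. Regions
#' outside the given breaks land in open-ended overflow bins.
#'
#' @param targets data.frame from [target_regions()].
#' @param genome a `reference_genome`.
#' @param per_target_depth numeric vector aligned with `targets` rows.
#' @param breaks interior GC-bin boundaries (default 0.3 / 0.5 / 0.7).
#' @return data.frame with `bin`, `gc_lo`, `gc_hi`, `n`, `mean_depth`.
#' @export
gc_depth_table <- function(targets, genome, per_target_depth,
                           breaks = c(0.3, 0.5, 0.7)) {
  gc <- vapply(seq_len(nrow(targets)), function(i)
    gc_fraction(genome_subseq(genome, targets$contig[i], targets$start0[i],
                              targets$end0[i])), numeric(1))
  edges <- c(0, breaks, 1)
  bin <- cut(gc, breaks = edges, include.lowest = TRUE, right = FALSE)
  # right = FALSE makes bins [lo, hi); force gc == 1 into the top bin
  bin[gc == 1] <- levels(bin)[length(levels(bin))]
  agg <- data.frame(
    bin = levels(bin),
    gc_lo = edges[-length(edges)],
    gc_hi = edges[-1],
    n = as.integer(table(bin)),
    mean_depth = as.numeric(tapply(per_target_depth, bin, mean)[levels(bin)])
  )
  agg$mean_depth[is.na(agg$mean_depth) & agg$n == 0L] <- NA_real_
  rownames(agg) <- NULL
  agg
}

#' Concordance between two SNP call sets
#'
#' Intersects by (contig, pos0, alt) and reports shared counts and the
#' shared fraction relative to each set.
#'
#' @param a,b data.frames with `contig`, `pos0`, `alt`.
#' @return list with `shared`, `only_a`, `only_b`, `frac_a`, `frac_b`.
#' @export
snp_concordance <- function(a, b) {
  ka <- unique(paste(a$contig, a$pos0, a$alt, sep = "\r"))
  kb <- unique(paste(b$contig, b$pos0, b$alt, sep = "\r"))
  shared <- length(intersect(ka, kb))
  list(shared = shared,
       only_a = length(ka) - shared,
       only_b = length(kb) - shared,
       frac_a = if (length(ka)) shared / length(ka) else NA_real_,
       frac_b = if (length(kb)) shared / length(kb) else NA_real_)
}

#' Full capture QC report
#'
#' Runs read filtering, base classification, depth profiling, uniformity and
#' GC-depth analyses and returns the aggregate report.
#'
#' @param reads a `read_set`.
#' @param snps target SNPs (data.frame with `id`, `contig`, `pos0`).
#' @param genome a `reference_genome`.
#' @param flank target flank extent (bp).
#' @param min_depth per-target depth at or above which a target counts as
#'   covered.
#' @param ... passed to [filter_reads()].
#' @return list of class `capture_qc_report` with elements `read_tally`,
#'   `bases` (from [classify_alignment_bases()]), `fractions`, `profile`,
#'   `per_target_depth`, `mean_target_depth`, `target_coverage` (fraction of
#'   targets with depth >= `min_depth`), `uniformity`, `gc_table`, and
#'   `bait_footprint` (merged target footprint in bp).
#' @export
capture_qc_report <- function(reads, snps, genome, flank = 300L,
                              min_depth = 4L, ...) {
  targets <- target_regions(snps, genome, flank = flank)
  filt <- filter_reads(reads, ...)
  bases <- classify_alignment_bases(filt$reads, targets)
  prof <- depth_profile(filt$reads, targets, genome, flank = flank)
  unif <- coverage_uniformity(prof$snp_depth)
  gc_tab <- gc_depth_table(targets, genome, prof$snp_depth)
  footprint <- sum(interval_width(interval_merge(
    interval_set(targets$contig, targets$start0, targets$end0))))
  structure(list(
    read_tally = filt$tally,
    bases = bases,
    fractions = c(aligned = unname(bases["aligned"] / bases["total"]),
                  unique = unname(bases["unique"] / bases["total"]),
                  on_flank = unname(bases["on_flank"] / bases["total"]),
                  off_target = unname(bases["off_target"] / bases["total"]),
                  on_flank_of_aligned = unname(bases["on_flank"] / bases["aligned"])),
    profile = prof,
    per_target_depth = prof$snp_depth,
    mean_target_depth = mean(prof$snp_depth, na.rm = TRUE),
    target_coverage = mean(prof$snp_depth >= min_depth, na.rm = TRUE),
    uniformity = unif,
    gc_table = gc_tab,
    bait_footprint = footprint
  ), class = "capture_qc_report")
}

#' @export
print.capture_qc_report <- function(x, ...) {
  cat("capture_qc_report\n")
  cat(sprintf("  total bases        %d\n", as.integer(x$bases["total"])))
  cat(sprintf("  aligned            %.1f%%\n", 100 * x$fractions["aligned"]))
  cat(sprintf("  uniquely aligned   %.1f%%\n", 100 * x$fractions["unique"]))
  cat(sprintf("  on flanking region %.1f%%\n", 100 * x$fractions["on_flank"]))
  cat(sprintf("  off target         %.1f%%\n", 100 * x$fractions["off_target"]))
  cat(sprintf("  mean target depth  %.1fX\n", x$mean_target_depth))
  cat(sprintf("  target coverage    %.1f%%\n", 100 * x$target_coverage))
  cat(sprintf("  uniformity >=0.4x %.1f%%, >=0.8x %.1f%%\n",
              100 * x$uniformity$fractions[1], 100 * x$uniformity$fractions[2]))
  invisible(x)
}
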