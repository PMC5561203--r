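# Bait enumeration and probe selection. A probe is a 120-mer oligo: a 90-bp
# genome-complementary bait flanked by two fixed 15-bp PCR primer arms.

#' Fixed PCR primer arms of the 120-mer probe
#'
#' @format character scalars of 15 bases each.
#' @export
ARM_A <- "GAAGCGAGGATCAAC"

#' @rdname ARM_A
#' @export
ARM_B <- "CATTGCGTGAACCGA"

#' Probe design parameters
#'
#' @param bait_len bait length in bp.
#' @param max_center_offset maximum distance (bp) from bait center to the
#'   target SNP.
#' @param target_offset preferred |center offset| (bp); probes closest to it
#'   rank best.
#' @param gc_range inclusive viable GC-fraction range.
#' @param n_select number of best probes kept per SNP (2 or 3).
#' @param min_viable SNPs with fewer viable probes are dropped (subject to
#'   the two-probe hairpin rescue).
#' @param min_stem,min_loop hairpin screen applied to each bait.
#' @return list of class `design_params`.
#' @export
design_params <- function(bait_len = 90L, max_center_offset = 50L,
                          target_offset = 20L, gc_range = c(0.30, 0.70),
                          n_select = 2L, min_viable = 2L,
                          min_stem = 9L, min_loop = 3L) {
  stopifnot(target_offset <= max_center_offset,
            gc_range[1] >= 0, gc_range[2] <= 1, gc_range[1] <= gc_range[2],
            n_select %in% 2:3)
  structure(list(bait_len = as.integer(bait_len),
                 max_center_offset = as.integer(max_center_offset),
                 target_offset = as.integer(target_offset),
                 gc_range = gc_range, n_select = as.integer(n_select),
                 min_viable = as.integer(min_viable),
                 min_stem = as.integer(min_stem),
                 min_loop = as.integer(min_loop)),
            class = "design_params")
}

#' GC fraction of a sequence
#'
#' (G + C) / (A + C + G + T); N is excluded from the denominator. Vectorized.
#'
#' @param seq character vector of sequences.
#' @return numeric vector in \[0, 1\]; `NaN` for all-N sequences.
#' @export
gc_fraction <- function(seq) {
  stopifnot(all(nzchar(seq)))
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seq),
                                          baseOnly = TRUE)
  acgt <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  unname((counts[, "C"] + counts[, "G"]) / acgt)
}

#' Enumerate candidate baits covering a SNP
#'
#' One candidate per bait start such that the bait contains the SNP and the
#' bait center lies within `max_center_offset` bp of it. For a 90-bp bait
#' every covering placement has |center offset| <= 45, so 90 candidates are
#' produced away from contig edges. Each candidate carries its GC fraction
#' and hairpin flag; candidates outside the GC range, containing N, or
#' hairpin-containing are marked accordingly (`viable` requires GC and no N;
#' the hairpin flag is kept separate for the selection-stage rescue rule).
#'
#' @param genome a `reference_genome`.
#' @param contig,pos0 SNP coordinates.
#' @param params a [design_params()].
#' @return data.frame with `bait_start0`, `bait_seq`, `center_offset`,
#'   `gc`, `has_n`, `hairpin`, `gc_ok`, `placement_ok`, `viable`.
#' @export
enumerate_baits <- function(genome, contig, pos0, params = design_params()) {
  B <- params$bait_len
  clen <- genome$lengths[[contig]]
  starts <- seq.int(max(0L, pos0 - B + 1L), min(pos0, clen - B))
  if (length(starts) == 0L || starts[1] > pos0) {
    return(data.frame(bait_start0 = integer(), bait_seq = character(),
                      center_offset = integer(), gc = numeric(),
                      has_n = logical(), hairpin = logical(),
                      gc_ok = logical(), placement_ok = logical(),
                      viable = logical()))
  }
  seqs <- vapply(starts, function(s) genome_subseq(genome, contig, s, s + B),
                 character(1))
  center_offset <- (starts + B %/% 2L) - pos0
  gc <- gc_fraction(seqs)
  has_n <- grepl("N", seqs, fixed = TRUE)
  hairpin <- vapply(seqs, function(s)
    !is.null(detect_hairpin(s, params$min_stem, params$min_loop)), logical(1))
  gc_ok <- !has_n & !is.nan(gc) &
    gc >= params$gc_range[1] & gc <= params$gc_range[2]
  placement_ok <- abs(center_offset) <= params$max_center_offset
  data.frame(bait_start0 = starts, bait_seq = seqs,
             center_offset = center_offset, gc = gc, has_n = has_n,
             hairpin = hairpin, gc_ok = gc_ok, placement_ok = placement_ok,
             viable = gc_ok & placement_ok & !hairpin,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the best probes for one SNP
#'
#' Viable candidates are ranked by |(|center offset|) - target_offset|
#' ascending (probes about `target_offset` bp off-center rank best), ties by
#' |GC - 0.5|, then by leftmost start; the top `n_select` are kept at one
#' copy each. A SNP with fewer than `min_viable` viable candidates is
#' dropped, except the hairpin rescue: when exactly two candidates pass the
#' GC/placement screens and exactly one of those carries a hairpin, the
#' other is kept alone at two copies. Any selected probe covering two or
#' more target SNPs also has its copies doubled (applied in [design_all()]).
#'
#' @param candidates data.frame from [enumerate_baits()].
#' @param params a [design_params()].
#' @return list with `selected` (data.frame of chosen candidates plus
#'   `copies`) and `verdict` (`"OK"`, `"RESCUED"`, `"NO_PROBE"`,
#'   `"ONE_PROBE"`).
#' @export
select_probes <- function(candidates, params = design_params()) {
  none <- list(selected = cbind(candidates[0, , drop = FALSE],
                                copies = integer()),
               verdict = "NO_PROBE")
  if (nrow(candidates) == 0L) return(none)
  gp <- candidates[candidates$gc_ok & candidates$placement_ok, , drop = FALSE]
  viable <- gp[!gp$hairpin, , drop = FALSE]
  if (nrow(viable) >= params$min_viable) {
    key1 <- abs(abs(viable$center_offset) - params$target_offset)
    key2 <- abs(viable$gc - 0.5)
    ord <- order(key1, key2, viable$bait_start0)
    sel <- viable[head(ord, params$n_select), , drop = FALSE]
    sel$copies <- 1L
    rownames(sel) <- NULL
    return(list(selected = sel, verdict = "OK"))
  }
  if (nrow(gp) == 2L && sum(gp$hairpin) == 1L) {
    sel <- gp[!gp$hairpin, , drop = FALSE]
    sel$copies <- 2L
    rownames(sel) <- NULL
    return(list(selected = sel, verdict = "RESCUED"))
  }
  if (nrow(viable) == 1L) {
    none$verdict <- "ONE_PROBE"
  }
  none
}

#' Build the 120-mer synthesis oligo from a bait
#'
#' @param bait character scalar of exactly `bait_len` (90) bases.
#' @param bait_len expected bait length.
#' @return character scalar of length 120: `ARM_A + bait + ARM_B`.
#' @export
build_oligo <- function(bait, bait_len = 90L) {
  if (any(nchar(bait) != bait_len))
    stop("bait must be exactly ", bait_len, " bp")
  paste0(ARM_A, bait, ARM_B)
}

#' Design probes for a screened SNP set
#'
#' Runs [enumerate_baits()] and [select_probes()] per SNP, doubles copies of
#' probes whose bait covers two or more target SNPs, and assembles the final
#' oligo order.
#'
#' @param snps data.frame with `id`, `contig`, `pos0` (screen survivors).
#' @param genome a `reference_genome`.
#' @param params a [design_params()].
#' @return list of class `probe_design`: `probes` (data.frame with
#'   `probe_id`, `snp_id`, `contig`, `bait_start0`, `strand`, `center_offset`,
#'   `gc`, `bait_seq`, `oligo_seq`, `covers`, `copies`), `tally` (named:
#'   `designed`, `dropped_no_probe`, `dropped_one_probe`, `rescued`,
#'   `multi_snp_doubled`), and `kept` (ids of SNPs with probes).
#' @export
design_all <- function(snps, genome, params = design_params()) {
  rows <- vector("list", nrow(snps))
  verdicts <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    cand <- enumerate_baits(genome, snps$contig[i], snps$pos0[i], params)
    res <- select_probes(cand, params)
    verdicts[i] <- res$verdict
    if (nrow(res$selected)) {
      sel <- res$selected
      sel$snp_id <- snps$id[i]
      sel$contig <- snps$contig[i]
      rows[[i]] <- sel
    }
  }
  probes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(probes)) {
    probes <- data.frame(snp_id = character(), contig = character(),
                         bait_start0 = integer(), center_offset = integer(),
                         gc = numeric(), bait_seq = character(),
                         copies = integer(), stringsAsFactors = FALSE)
  }
  # a bait covers every target SNP inside its span
  n_multi <- 0L
  if (nrow(probes)) {
    pos_by_contig <- split(snps$pos0, snps$contig)
    covers <- mapply(function(ct, s) {
      p <- pos_by_contig[[ct]]
      sum(p >= s & p < s + params$bait_len)
    }, probes$contig, probes$bait_start0)
    probes$covers <- as.integer(covers)
    multi <- probes$covers >= 2L
    probes$copies[multi] <- probes$copies[multi] * 2L
    n_multi <- sum(multi)
    probes$oligo_seq <- build_oligo(probes$bait_seq, params$bait_len)
    probes$strand <- "+"
    probes$probe_id <- sprintf("%s_p%d", probes$snp_id,
                               as.integer(stats::ave(seq_len(nrow(probes)),
                                                     probes$snp_id,
                                                     FUN = seq_along)))
    probes <- probes[, c("probe_id", "snp_id", "contig", "bait_start0",
                         "strand", "center_offset", "gc", "bait_seq",
                         "oligo_seq", "covers", "copies")]
    rownames(probes) <- NULL
  }
  tally <- c(designed = sum(verdicts %in% c("OK", "RESCUED")),
             dropped_no_probe = sum(verdicts == "NO_PROBE"),
             dropped_one_probe = sum(verdicts == "ONE_PROBE"),
             rescued = sum(verdicts == "RESCUED"),
             multi_snp_doubled = n_multi)
  structure(list(probes = probes, tally = tally,
                 kept = unique(probes$snp_id)),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat("probe_design:", nrow(x$probes), "probes for", length(x$kept),
      "SNPs\n")
  cat(paste(names(x$tally), x$tally, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
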