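# Window-based density optimization. SNP-dense regions are thinned to about
# one SNP per 40-kb window using a triangular, MAF-weighted ranking score.

#' Window ranking score of a SNP
#'
#' `score = maf * (E - S) * (1 - |a - (E-S)/2| / ((E-S)/2))`
#'
#' where `S` and `E` are the window's start and stop coordinates, and `a` is
#' the SNP's offset within the window (bp from `S`). The weight is
#' triangular: 1 at the window center, 0 at either edge, so the score peaks
#' at `maf * (E - S)` for a centered SNP. Vectorized over all arguments.
#'
#' @param maf folded minor allele frequency in \[0, 0.5\].
#' @param a SNP offset within the window, `0 <= a < E - S`.
#' @param S,E window start and stop coordinates (`S < E`).
#' @return non-negative score, at most `maf * (E - S)`.
#' @export
rank_score <- function(maf, a, S, E) {
  W <- E - S
  stopifnot(all(W > 0), all(a >= 0 & a < W), all(maf >= 0 & maf <= 0.5))
  half <- W / 2
  maf * W * (1 - abs(a - half) / half)
}

#' Assign SNPs to consecutive genomic windows and score them
#'
#' Windows of width `W` tile each contig contiguously from coordinate 0; the
#' last window of a contig is truncated to the contig end and uses its true
#' width in the score.
#'
#' @param snps data.frame with `id`, `contig`, `pos0`, `maf`.
#' @param genome a `reference_genome` (for contig lengths).
#' @param W window width in bp (default 40000).
#' @return the input data.frame with added columns `win_index`, `win_S`,
#'   `win_E`, `a` (offset from `win_S`) and `score`.
#' @export
assign_windows <- function(snps, genome, W = 40000L) {
  idx <- snps$pos0 %/% W
  S <- idx * W
  E <- pmin(S + W, genome$lengths[snps$contig])
  out <- snps
  out$win_index <- idx
  out$win_S <- as.integer(S)
  out$win_E <- as.integer(E)
  out$a <- snps$pos0 - out$win_S
  out$score <- rank_score(snps$maf, out$a, out$win_S, out$win_E)
  out
}

#' Thin windows to their top-scoring SNPs
#'
#' Keeps at most `max_per_window` SNPs per (contig, window), choosing the
#' highest ranking scores; ties go to the SNP nearer the window center, then
#' to the lower coordinate. Whitelisted SNPs are exempt from thinning and
#' are re-added (deduplicated by contig and position) afterwards.
#'
#' @param scored data.frame from [assign_windows()].
#' @param max_per_window SNPs retained per window (default 1).
#' @param whitelist optional data.frame with `contig`, `pos0` (and ideally
#'   `id`, `maf`) of SNPs that bypass thinning.
#' @return data.frame of kept SNPs (same columns as `scored`, plus logical
#'   `whitelisted`).
#' @export
thin_windows <- function(scored, max_per_window = 1L, whitelist = NULL) {
  if (nrow(scored)) {
    key <- paste(scored$contig, scored$win_index, sep = "\r")
    half_dist <- abs(scored$a - (scored$win_E - scored$win_S) / 2)
    ord <- order(key, -scored$score, half_dist, scored$pos0)
    o <- scored[ord, , drop = FALSE]
    rank_in_win <- stats::ave(seq_len(nrow(o)), key[ord], FUN = seq_along)
    kept <- o[rank_in_win <= max_per_window, , drop = FALSE]
  } else {
    kept <- scored
  }
  kept$whitelisted <- FALSE
  if (!is.null(whitelist) && nrow(whitelist)) {
    wl <- whitelist[!duplicated(paste(whitelist$contig, whitelist$pos0)), ,
                    drop = FALSE]
    new <- !(paste(wl$contig, wl$pos0) %in% paste(kept$contig, kept$pos0))
    if (any(new)) {
      add <- wl[new, , drop = FALSE]
      for (col in setdiff(names(kept), names(add))) add[[col]] <- NA
      add$whitelisted <- TRUE
      kept <- rbind(kept, add[, names(kept), drop = FALSE])
    }
  }
  kept <- kept[order(kept$contig, kept$pos0), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Nearest-neighbor spacing statistics of a SNP set
#'
#' For every SNP, the distance to its closest same-contig neighbor; reports
#' a binned histogram and the fraction of spacings inside `[lo, hi]`
#' (defaults 15-70 kb). Contigs carrying a single SNP contribute no
#' distance and are counted separately.
#'
#' @param snps data.frame with `contig`, `pos0`.
#' @param lo,hi inclusive bounds of the reported spacing band (bp).
#' @param binwidth histogram bin width (bp).
#' @return list with `distances` (per-SNP nearest-neighbor distance),
#'   `fraction_in_band`, `histogram` (data.frame `bin_lo`, `bin_hi`, `n`),
#'   `n_singleton_contigs`.
#' @export
spacing_stats <- function(snps, lo = 15000, hi = 70000, binwidth = 5000) {
  dists <- unlist(lapply(split(snps$pos0, snps$contig), function(p) {
    if (length(p) < 2L) return(numeric())
    p <- sort(p)
    gaps <- diff(p)
    pmin(c(Inf, gaps), c(gaps, Inf))
  }), use.names = FALSE)
  n_single <- sum(vapply(split(snps$pos0, snps$contig), length,
                         integer(1)) == 1L)
  frac <- if (length(dists)) mean(dists >= lo & dists <= hi) else NA_real_
  hist_df <- if (length(dists)) {
    b <- dists %/% binwidth
    tab <- table(b)
    data.frame(bin_lo = as.integer(names(tab)) * binwidth,
               bin_hi = (as.integer(names(tab)) + 1L) * binwidth,
               n = as.integer(tab))
  } else {
    data.frame(bin_lo = integer(), bin_hi = integer(), n = integer())
  }
  list(distances = dists, fraction_in_band = frac, histogram = hist_df,
       n_singleton_contigs = n_single)
}
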