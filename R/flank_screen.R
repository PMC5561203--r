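# Flank screening: hairpin-free flanks, k-mer-unique flanks, repeat
# exclusion. These are the three initial screens a candidate SNP must pass
# before bait design.

#' Extract SNP flanking sequences
#'
#' For each SNP, the left flank is the `flank` bases immediately upstream of
#' the SNP and the right flank the `flank` bases immediately downstream; the
#' SNP base itself is excluded. SNPs whose flanks would cross a contig edge
#' are flagged not-ok (and are screened out downstream).
#'
#' @param genome a `reference_genome`.
#' @param contig,pos0 vectors of SNP contigs and 0-based positions.
#' @param flank flank length in bp (default 150).
#' @return list with character vectors `left`, `right` (NA when truncated)
#'   and logical `ok`.
#' @export
extract_flanks <- function(genome, contig, pos0, flank = 150L) {
  n <- length(pos0)
  stopifnot(length(contig) == n)
  left <- right <- rep(NA_character_, n)
  clen <- genome$lengths[contig]
  ok <- !is.na(clen) & pos0 - flank >= 0L & pos0 + 1L + flank <= clen
  for (i in which(ok)) {
    left[i] <- genome_subseq(genome, contig[i], pos0[i] - flank, pos0[i])
    right[i] <- genome_subseq(genome, contig[i], pos0[i] + 1L,
                              pos0[i] + 1L + flank)
  }
  list(left = left, right = right, ok = as.logical(ok))
}

#' Detect the longest hairpin (stem-loop) in an oligonucleotide
#'
#' A hairpin is two non-overlapping arms within the sequence where the
#' downstream arm is the exact reverse complement of the upstream arm
#' (stem length >= `min_stem`) separated by at least `min_loop` intervening
#' bases. The default `min_stem = 9` rejects stems longer than 8 bp, the
#' hybridization-impairing regime; 8-bp stems pass. N matches no base, so
#' arms containing N never pair. No mismatches or bulges are modelled.
#'
#' Search strategy: all seed pairs of `min_stem`-mers whose downstream member
#' equals the reverse complement of the upstream member are found by hashing,
#' then each seed is extended outward while bases keep complementing, to
#' report the longest stem.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param min_stem minimum stem length in bp that counts as a hairpin.
#' @param min_loop minimum number of bases between the arms.
#' @return `NULL` when no hairpin exists, else a list with `stem`, `left0`
#'   (0-based start of the upstream arm), `right0` (0-based start of the
#'   downstream arm) and `loop` (bases between the arms) for a longest hit.
#' @export
detect_hairpin <- function(seq, min_stem = 9L, min_loop = 3L) {
  n <- nchar(seq)
  if (n < 2L * min_stem + min_loop) return(NULL)
  k <- min_stem
  subs <- substring(seq, 1:(n - k + 1L), k:n)
  has_n <- grepl("N", subs, fixed = TRUE)
  rc <- rc_chr(subs)
  # seed pairs: subs[j] == rc[i] with j - i >= k + min_loop
  idx <- split(seq_along(subs), subs)
  best <- NULL
  chars <- comp <- NULL
  for (i in which(!has_n)) {
    js <- idx[[rc[i]]]
    if (is.null(js)) next
    js <- js[js >= i + k + min_loop & !has_n[js]]
    if (length(js) && is.null(chars)) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "")[chars]
      comp[is.na(comp)] <- ""
    }
    for (j in js) {
      # extend outward: upstream arm grows left, downstream arm grows right
      L <- k
      a <- i - 1L          # next upstream base (1-based)
      b <- j + k           # next downstream base (1-based)
      while (a >= 1L && b <= n && comp[a] == chars[b] && nzchar(comp[a])) {
        L <- L + 1L; a <- a - 1L; b <- b + 1L
      }
      if (is.null(best) || L > best$stem) {
        best <- list(stem = L, left0 = a, right0 = j - 1L,
                     loop = (j - 1L) - (a + L))
      }
    }
  }
  best
}

#' Build a canonical k-mer multiplicity index over a genome
#'
#' Counts every k-mer of the genome after strand collapsing (a k-mer and its
#' reverse complement share one canonical key, the lexicographic minimum).
#' k-mers containing N are skipped.
#'
#' @param genome a `reference_genome`.
#' @param k k-mer length (default 30).
#' @return object of class `kmer_index`: a list with `counts` (named integer
#'   vector, canonical k-mer -> multiplicity) and `k`.
#' @export
kmer_index <- function(genome, k = 30L) {
  all_kmers <- unlist(lapply(genome$sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  all_kmers <- all_kmers[!grepl("N", all_kmers, fixed = TRUE)]
  canon <- pmin(all_kmers, revcomp(all_kmers))
  dt <- data.table::data.table(kmer = canon)
  dt <- dt[, list(count = .N), by = "kmer"]
  structure(list(counts = setNames(dt$count, dt$kmer), k = as.integer(k)),
            class = "kmer_index")
}

#' Fraction of a sequence's k-mers that are genome-unique
#'
#' Looks every canonical k-mer of `seq` up in the genome index and returns
#' the fraction with multiplicity exactly 1. k-mers containing N are excluded
#' from both numerator and denominator; a sequence with no N-free k-mer
#' errors.
#'
#' @param index a [kmer_index()].
#' @param seq character scalar; must be at least k long.
#' @return fraction in \[0, 1\].
#' @export
kmer_uniqueness <- function(index, seq) {
  k <- index$k
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k = ", k)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) stop("no N-free k-mers in sequence")
  canon <- pmin(kmers, rc_chr(kmers))
  counts <- unname(index$counts[canon])
  counts[is.na(counts)] <- 0L  # absent from genome: not unique in it
  mean(counts == 1L)
}

#' Does a SNP fall inside a repeat?
#'
#' Point overlap of the SNP base against the repeat annotation (half-open: a
#' SNP at an interval's end coordinate is outside).
#'
#' @param repeats an `interval_set` of repeat annotations.
#' @param contig,pos0 SNP coordinates (vectorized).
#' @return logical vector.
#' @export
repeat_overlap <- function(repeats, contig, pos0) {
  interval_overlaps_point(repeats, contig, pos0)
}

#' Screen candidate SNPs on their flanks
#'
#' Applies the three design screens to each candidate: (1) neither flank may
#' contain a hairpin with stem longer than 8 bp; (2) both flanks must be
#' unique in the genome (canonical k-mer uniqueness fraction at or above
#' `uniqueness_min`); (3) the SNP must not lie in a repeat. SNPs with
#' edge-truncated flanks are screened out. The tally assigns each screened
#' SNP its first firing flag in the order EDGE, REPEAT, HAIRPIN, NON_UNIQUE.
#'
#' @param candidates a `candidate_set` from [filter_cohort()], or a
#'   data.frame with columns `id`, `contig`, `pos0`, `maf`, `flank_left`,
#'   `flank_right`, `flank_ok`.
#' @param genome a `reference_genome` (for the k-mer index).
#' @param repeats an `interval_set` of repeats (may be empty).
#' @param k k-mer length for the uniqueness screen.
#' @param min_stem,min_loop hairpin parameters (see [detect_hairpin()]).
#' @param uniqueness_min minimum uniqueness fraction per flank.
#' @param index optional prebuilt [kmer_index()] (rebuilt from `genome`
#'   otherwise).
#' @return list of class `screen_result`: `snps` (survivors, same columns as
#'   input), `flags` (data.frame of per-SNP logical flags), `tally` (named
#'   integer: EDGE, REPEAT, HAIRPIN, NON_UNIQUE), `n_input`.
#' @export
screen_candidates <- function(candidates, genome, repeats = interval_set(),
                              k = 30L, min_stem = 9L, min_loop = 3L,
                              uniqueness_min = 0.95, index = NULL) {
  snps <- if (inherits(candidates, "candidate_set")) candidates$snps else candidates
  n <- nrow(snps)
  if (n == 0L) {
    return(structure(list(snps = snps,
                          flags = data.frame(),
                          tally = c(EDGE = 0L, REPEAT = 0L, HAIRPIN = 0L,
                                    NON_UNIQUE = 0L),
                          n_input = 0L),
                     class = "screen_result"))
  }
  if (is.null(index)) index <- kmer_index(genome, k = k)
  edge <- !snps$flank_ok
  in_repeat <- repeat_overlap(repeats, snps$contig, snps$pos0)
  hairpin <- non_unique <- rep(FALSE, n)
  for (i in which(!edge)) {
    hairpin[i] <-
      !is.null(detect_hairpin(snps$flank_left[i], min_stem, min_loop)) ||
      !is.null(detect_hairpin(snps$flank_right[i], min_stem, min_loop))
    non_unique[i] <-
      kmer_uniqueness(index, snps$flank_left[i]) < uniqueness_min ||
      kmer_uniqueness(index, snps$flank_right[i]) < uniqueness_min
  }
  flags <- data.frame(id = snps$id, EDGE = edge, REPEAT = in_repeat,
                      HAIRPIN = hairpin, NON_UNIQUE = non_unique,
                      stringsAsFactors = FALSE)
  first <- rep(NA_character_, n)
  for (f in c("EDGE", "REPEAT", "HAIRPIN", "NON_UNIQUE"))
    first[is.na(first) & flags[[f]]] <- f
  keep <- is.na(first)
  tally <- table(factor(first[!keep],
                        levels = c("EDGE", "REPEAT", "HAIRPIN", "NON_UNIQUE")))
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(snps = out, flags = flags, tally = c(tally), n_input = n),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", nrow(x$snps), "of", x$n_input, "SNPs pass;",
      "rejections:", paste(names(x$tally), x$tally, collapse = ", "), "\n")
  invisible(x)
}
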