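# Independent brute-force oracles used to cross-check the implementation.
# These share no code with the package internals.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

random_dna_str <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# reverse complement by explicit per-character table lookup
oracle_rc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- rev(unname(COMP[ch]))
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# hairpin verdict by direct definition: does any pair of k-mer positions
# (i, j) exist with seq[j..j+k-1] the reverse complement of seq[i..i+k-1]
# and at least min_loop bases between the arms?  (Any stem of length >= k
# contains such a k-seed with the same gap, so this decides existence.)
oracle_hairpin <- function(seq, min_stem = 9L, min_loop = 3L) {
  n <- nchar(seq)
  k <- min_stem
  if (n < 2L * k + min_loop) return(FALSE)
  subs <- substring(seq, 1:(n - k + 1L), k:n)
  ok <- !grepl("N", subs, fixed = TRUE)
  rc <- vapply(subs, oracle_rc, character(1), USE.NAMES = FALSE)
  m <- length(subs)
  for (i in seq_len(m)) {
    if (!ok[i]) next
    js <- seq_len(m)
    js <- js[js >= i + k + min_loop & ok[js]]
    if (any(subs[js] == rc[i])) return(TRUE)
  }
  FALSE
}

# plant a stem-loop (stem of `stem` bp, loop of `loop` bp) at a random
# offset of a random background of length n
plant_stem <- function(n, stem, loop = 3L) {
  arm <- sample(BASES, stem, replace = TRUE)
  unit <- c(arm, sample(BASES, loop, replace = TRUE), rev(unname(COMP[arm])))
  bg <- sample(BASES, n, replace = TRUE)
  at <- sample.int(n - length(unit) + 1L, 1L)
  bg[at:(at + length(unit) - 1L)] <- unit
  paste(bg, collapse = "")
}

# literal re-evaluation of the hard-filter OR-expression on a record's
# INFO values (absent keys never trigger)
oracle_hard_filter_fails <- function(info) {
  g <- function(k) if (k %in% names(info)) info[[k]] else NA_real_
  any(c(g("QD") < 2.0, g("FS") > 60.0, g("MQ") < 40.0,
        g("MQRankSum") < -12.5, g("ReadPosRankSum") < -8.0), na.rm = TRUE)
}

# linear-scan point-in-interval oracle
oracle_point_overlap <- function(df, contig, pos0) {
  any(df$contig == contig & df$start0 <= pos0 & pos0 < df$end0)
}

# exhaustive per-window thinning oracle: floor-assign, then argmax score
# with ties by centrality then coordinate
oracle_thin <- function(contig, pos0, score, a, W_eff, W = 40000) {
  key <- paste(contig, pos0 %/% W)
  keep <- unlist(lapply(split(seq_along(pos0), key), function(ix) {
    cent <- abs(a[ix] - W_eff[ix] / 2)
    ix[order(-score[ix], cent, pos0[ix])][1]
  }))
  sort(unname(keep))
}

# a genome stub carrying only contig lengths (enough for window logic)
length_only_genome <- function(lengths) {
  structure(list(sequences = NULL, lengths = lengths),
            class = "reference_genome")
}
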