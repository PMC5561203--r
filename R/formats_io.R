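# Format boundary: every other module consumes only the domain objects built
# here. Internal coordinates are 0-based half-open throughout; VCF positions
# are converted at this boundary only.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and contig order is preserved. Lowercase (soft
#' masked) input is permitted; masking is not retained.
#'
#' @param path path to a FASTA file.
#' @return An object of class `reference_genome`: a list with `sequences`
#'   (named character vector over A/C/G/T/N) and `lengths` (named integer).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  reference_genome(setNames(toupper(as.character(set)), nm))
}

#' Construct a reference genome from named sequences
#'
#' @param sequences named character vector of contig sequences.
#' @return a `reference_genome`.
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("contigs must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate contig name: ", names(sequences)[duplicated(names(sequences))][1])
  if (any(!nzchar(sequences))) stop("empty sequence")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("non-ACGTN characters in contig ", names(sequences)[bad][1])
  structure(list(sequences = sequences,
                 lengths = setNames(nchar(sequences), names(sequences))),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "contig(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Extract a genome subsequence
#'
#' @param genome a `reference_genome`.
#' @param contig contig name.
#' @param start0,end0 0-based half-open interval; must lie within the contig.
#' @return character scalar of exactly `end0 - start0` bases.
#' @export
genome_subseq <- function(genome, contig, start0, end0) {
  seq <- unname(genome$sequences[contig])
  if (is.na(seq)) stop("unknown contig: ", contig)
  if (start0 < 0 || end0 > nchar(seq) || start0 > end0)
    stop("interval [", start0, ",", end0, ") outside contig ", contig)
  substr(seq, start0 + 1L, end0)
}

#' Write a reference genome to FASTA
#'
#' @param genome a `reference_genome`.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

INFO_KEYS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP",
               "HaplotypeScore")

#' Read a cohort VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a site table plus genotype and
#' per-sample depth matrices. Multi-allelic sites are kept (downstream filters
#' tally them as `NOT_BIALLELIC`); phasing is ignored. Missing INFO keys are
#' `NA`, never 0.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @return An object of class `cohort_vcf`: a list with
#'   \describe{
#'     \item{sites}{data.frame with `contig`, `pos1`, `pos0`, `id`, `ref`,
#'       `alt` (comma-joined), `n_alt`, and numeric columns for the INFO keys
#'       QD, FS, MQ, MQRankSum, ReadPosRankSum, DP, HaplotypeScore.}
#'     \item{gt}{integer matrix (sites x samples): alt-allele dosage 0/1/2,
#'       `NA` for missing calls.}
#'     \item{depth}{integer matrix (sites x samples) of FORMAT/DP, `NA` when
#'       absent.}
#'     \item{samples}{character vector of sample names.}
#'   }
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos1 <- as.integer(fix[, "POS"])
  if (any(is.na(pos1)) || any(pos1 <= 0L)) stop("VCF position must be >= 1")
  sites <- data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos1 = pos1,
    pos0 = pos1 - 1L,
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  sites$n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  for (k in INFO_KEYS) {
    sites[[k]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = k, as.numeric = TRUE))
    )
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(gt_raw)) stop("VCF has no GT FORMAT field")
  gt <- parse_gt_matrix(gt_raw)
  depth <- if (is.null(dp_raw)) {
    matrix(NA_integer_, nrow(sites), ncol(gt))
  } else {
    matrix(as.integer(dp_raw), nrow = nrow(sites))
  }
  structure(list(sites = sites, gt = gt, depth = depth,
                 samples = colnames(gt_raw)),
            class = "cohort_vcf")
}

# "0/1", "0|1", "./." -> alt dosage; any allele index > 1 counts as non-ref
parse_gt_matrix <- function(gt_raw) {
  u <- unique(as.vector(gt_raw))
  dos <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
    if (length(al) != 2L || any(!grepl("^[0-9.]+$", al)))
      stop("malformed genotype string: ", g)
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al) > 0L)
  }, integer(1))
  m <- matrix(dos[match(as.vector(gt_raw), u)], nrow = nrow(gt_raw))
  colnames(m) <- colnames(gt_raw)
  m
}

#' Assemble a single variant record
#'
#' Convenience accessor turning row `i` of a [read_vcf()] object into the
#' per-site structure the record-level filters consume.
#'
#' @param vcf a `cohort_vcf`.
#' @param i row index.
#' @return list with `contig`, `pos1`, `pos0`, `ref`, `alt` (character vector
#'   of alt alleles), `info` (named numeric, absent keys dropped),
#'   `genotypes` (dosage 0/1/2/NA), `sample_depths`.
#' @export
vcf_record <- function(vcf, i) {
  s <- vcf$sites[i, ]
  info <- vapply(INFO_KEYS, function(k) s[[k]], numeric(1))
  variant_record(contig = s$contig, pos1 = s$pos1, ref = s$ref,
                 alt = strsplit(s$alt, ",", fixed = TRUE)[[1]],
                 info = info[!is.na(info)],
                 genotypes = vcf$gt[i, ], sample_depths = vcf$depth[i, ])
}

#' Construct a variant record
#'
#' @param contig contig name.
#' @param pos1 1-based position.
#' @param ref,alt reference allele and alt allele(s).
#' @param info named numeric vector; only present keys are stored.
#' @param genotypes per-sample alt dosage (0, 1, 2 or `NA` for missing).
#' @param sample_depths per-sample integer depths (`NA` allowed).
#' @return list of class `variant_record`.
#' @export
variant_record <- function(contig, pos1, ref, alt, info = numeric(),
                           genotypes = integer(), sample_depths = NULL) {
  if (pos1 < 1) stop("pos1 must be >= 1")
  if (is.null(sample_depths)) sample_depths <- rep(NA_integer_, length(genotypes))
  if (length(genotypes) != length(sample_depths))
    stop("genotypes and sample_depths lengths differ")
  structure(list(contig = contig, pos1 = as.integer(pos1),
                 pos0 = as.integer(pos1) - 1L,
                 ref = ref, alt = as.character(alt),
                 info = info[!is.na(info)],
                 genotypes = as.integer(genotypes),
                 sample_depths = as.integer(sample_depths)),
            class = "variant_record")
}

#' Write a cohort VCF
#'
#' Emits a minimal VCF 4.2 with the numeric INFO keys the pipeline uses and
#' GT:DP per sample. Inverse of [read_vcf()] for the fields it carries.
#'
#' @param vcf a `cohort_vcf`.
#' @param path output path.
#' @export
write_vcf <- function(vcf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            INFO_KEYS, ifelse(INFO_KEYS == "DP", "Integer", "Float"), INFO_KEYS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vcf$samples), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vcf$gt + 1L], nrow = nrow(vcf$gt))
  gt_str[is.na(vcf$gt)] <- "./."
  dp_str <- matrix(as.character(vcf$depth), nrow = nrow(vcf$depth))
  dp_str[is.na(vcf$depth)] <- "."
  for (i in seq_len(nrow(vcf$sites))) {
    s <- vcf$sites[i, ]
    vals <- vapply(INFO_KEYS, function(k) s[[k]], numeric(1))
    keep <- !is.na(vals)
    info <- if (any(keep)) {
      kk <- INFO_KEYS[keep]
      vv <- vals[keep]
      paste(vapply(seq_along(kk), function(j) {
        if (kk[j] == "DP") sprintf("%s=%d", kk[j], as.integer(vv[j]))
        else sprintf("%s=%.6g", kk[j], vv[j])
      }, character(1)), collapse = ";")
    } else "."
    writeLines(paste(c(s$contig, s$pos1, s$id, s$ref, s$alt, ".", ".", info,
                       "GT:DP", paste(gt_str[i, ], dp_str[i, ], sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---- BED ------------------------------------------------------------------

#' Read a BED file into an interval set
#'
#' BED is 0-based half-open; at least three columns are required.
#'
#' @param path path to a BED file.
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(interval_set())
  g <- rtracklayer::import(path, format = "BED")
  if (length(g) == 0L) return(interval_set())
  interval_set(as.character(GenomicRanges::seqnames(g)),
               GenomicRanges::start(g) - 1L,
               GenomicRanges::end(g))
}

#' Write an interval set as BED
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @param names optional per-interval name column.
#' @export
write_bed <- function(x, path, names = NULL) {
  df <- data.frame(x$contig, x$start0, x$end0)
  if (!is.null(names)) df$name <- names
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- SAM ------------------------------------------------------------------

#' Read alignment records from a headered SAM file
#'
#' Parses the mandatory SAM columns into a read table. Flag bits 0x4
#' (unmapped) and 0x400 (duplicate) are honored; CIGAR is not interpreted
#' beyond read length (capture QC credits full read spans). There is no
#' installed reader for text SAM (only BAM), so the eleven mandatory fields
#' are split directly.
#'
#' @param path path to a SAM file.
#' @param mapq_unique MAPQ at or above which an alignment counts as unique.
#' @return data.frame of class `read_set` with columns `qname`, `flag`,
#'   `contig`, `pos0`, `mapq`, `seq`, `qual`, `mapped`, `duplicate`, `unique`.
#' @export
read_sam <- function(path, mapq_unique = 30L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(structure(data.frame(qname = character(), flag = integer(),
                                contig = character(), pos0 = integer(),
                                mapq = integer(), seq = character(),
                                qual = character(), mapped = logical(),
                                duplicate = logical(), unique = logical(),
                                stringsAsFactors = FALSE),
                     class = c("read_set", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L))
    stop("SAM record with fewer than 11 fields at line ",
         which(lengths(parts) < 11L)[1])
  f <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(f(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  pos1 <- as.integer(f(4))
  df <- data.frame(
    qname = f(1), flag = flag, contig = f(3),
    pos0 = ifelse(mapped, pos1 - 1L, NA_integer_),
    mapq = as.integer(f(5)), seq = f(10), qual = f(11),
    mapped = mapped,
    duplicate = bitwAnd(flag, 1024L) != 0L,
    stringsAsFactors = FALSE
  )
  df$contig[!mapped] <- NA_character_
  df$unique <- df$mapped & df$mapq >= mapq_unique
  bad <- nchar(df$seq) != nchar(df$qual) & df$qual != "*"
  if (any(bad)) stop("SEQ/QUAL length mismatch for read ", df$qname[bad][1])
  class(df) <- c("read_set", "data.frame")
  df
}

#' Write alignment records as SAM
#'
#' @param reads a `read_set` (see [read_sam()]).
#' @param genome a `reference_genome` providing the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                       genome$lengths)), con)
  if (nrow(reads)) {
    writeLines(paste(reads$qname, reads$flag,
                     ifelse(reads$mapped, reads$contig, "*"),
                     ifelse(reads$mapped, reads$pos0 + 1L, 0L),
                     ifelse(reads$mapped, reads$mapq, 0L),
                     ifelse(reads$mapped, paste0(nchar(reads$seq), "M"), "*"),
                     "*", 0L, 0L, reads$seq, reads$qual, sep = "\t"), con)
  }
  invisible(path)
}

# ---- probe order ----------------------------------------------------------

#' Write a probe synthesis order
#'
#' Tab-separated order sheet (probe id, SNP id, contig, bait start, strand,
#' oligo sequence, copies) plus an optional FASTA of the oligos.
#'
#' @param probes data.frame from [design_all()] (`$probes`).
#' @param path output TSV path.
#' @param fasta_path optional FASTA output of oligo sequences.
#' @export
write_probe_order <- function(probes, path, fasta_path = NULL) {
  df <- probes[, c("probe_id", "snp_id", "contig", "bait_start0", "strand",
                   "oligo_seq", "copies")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    write_fasta(reference_genome(setNames(probes$oligo_seq, probes$probe_id)),
                fasta_path)
  }
  invisible(path)
}

#' Read a probe synthesis order written by [write_probe_order()]
#'
#' @param path TSV path.
#' @return data.frame with the order columns.
#' @export
read_probe_order <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(probe_id = "character", snp_id = "character",
                            contig = "character"))
}

# ---- shared sequence helpers ----------------------------------------------

#' Reverse complement of DNA strings
#'
#' Vectorized; N maps to N.
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# light-weight reverse complement for many short strings, avoiding
# DNAStringSet construction overhead in inner loops
rc_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}
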