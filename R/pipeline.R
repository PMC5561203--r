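# Stage orchestration: filter -> screen -> design -> thin (-> qc), with a
# funnel report mirroring the chip-design workflow.

#' Run the chip-design pipeline on in-memory objects
#'
#' Chains cohort filtering, flank screening, probe design and density
#' thinning, and (when reads are supplied) capture QC on the final chip
#' SNPs. The funnel report lists the surviving SNP count after every stage;
#' survivor counts are non-increasing (whitelist additions are reported
#' separately).
#'
#' @param genome a `reference_genome`.
#' @param vcf a `cohort_vcf`.
#' @param repeats an `interval_set` of repeat annotations.
#' @param thresholds a [filter_thresholds()].
#' @param screen_params list of arguments for [screen_candidates()] (`k`,
#'   `min_stem`, `min_loop`, `uniqueness_min`).
#' @param params a [design_params()].
#' @param window thinning window width (bp).
#' @param max_per_window SNPs kept per window.
#' @param whitelist optional data.frame of SNPs exempt from thinning.
#' @param reads optional `read_set` for capture QC of the final chip.
#' @param qc_flank,qc_min_depth capture QC parameters.
#' @return list of class `chip_design`: `funnel` (data.frame stage/count),
#'   `filter`, `screen`, `design`, `thinned` (final SNP data.frame),
#'   `spacing`, `probes` (order for kept SNPs), and `qc` (a
#'   `capture_qc_report` or NULL).
#' @export
run_pipeline <- function(genome, vcf, repeats = interval_set(),
                         thresholds = filter_thresholds(),
                         screen_params = list(), params = design_params(),
                         window = 40000L, max_per_window = 1L,
                         whitelist = NULL, reads = NULL,
                         qc_flank = 300L, qc_min_depth = 4L) {
  filt <- filter_cohort(vcf, thresholds, genome)
  scr <- do.call(screen_candidates,
                 c(list(filt, genome = genome, repeats = repeats),
                   screen_params))
  des <- design_all(scr$snps, genome, params)
  designed <- scr$snps[scr$snps$id %in% des$kept, , drop = FALSE]
  scored <- assign_windows(designed, genome, W = window)
  thinned <- thin_windows(scored, max_per_window = max_per_window,
                          whitelist = whitelist)
  probes <- des$probes[des$probes$snp_id %in% thinned$id, , drop = FALSE]
  spacing <- spacing_stats(thinned)
  qc <- NULL
  if (!is.null(reads)) {
    qc <- capture_qc_report(reads, thinned, genome, flank = qc_flank,
                            min_depth = qc_min_depth)
  }
  funnel <- data.frame(
    stage = c("input_sites", "post_filter", "post_screen", "post_design",
              "final_chip"),
    count = c(filt$n_input, nrow(filt$snps), nrow(scr$snps),
              nrow(designed), nrow(thinned)),
    stringsAsFactors = FALSE
  )
  structure(list(funnel = funnel, filter = filt, screen = scr, design = des,
                 thinned = thinned, spacing = spacing, probes = probes,
                 qc = qc),
            class = "chip_design")
}

#' @export
print.chip_design <- function(x, ...) {
  cat("chip_design funnel:\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-12s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  if (!is.na(x$spacing$fraction_in_band))
    cat(sprintf("  spacing in 15-70 kb: %.1f%%\n",
                100 * x$spacing$fraction_in_band))
  invisible(x)
}

#' Run the full synthetic study end to end
#'
#' Generates the synthetic genome, cohort VCF and repeat annotation, runs
#' the design pipeline, simulates capture reads over the final chip SNPs
#' and computes the capture QC report.
#'
#' @param config a [synthetic_config()].
#' @param ... passed on to [run_pipeline()].
#' @return the [run_pipeline()] result, with the generator `truth` tables
#'   attached as `truth_snps` and `truth_reads`.
#' @export
run_synthetic_study <- function(config = synthetic_config(), ...) {
  g <- make_genome(config)
  vcf <- make_cohort_vcf(g$genome, g$truth, config)
  res <- run_pipeline(g$genome, vcf, g$repeats, ...)
  sim <- make_capture_reads(g$genome, res$thinned, config)
  res$qc <- capture_qc_report(sim$reads, res$thinned, g$genome)
  res$truth_snps <- g$truth
  res$truth_reads <- sim$truth
  res
}

#' Run the pipeline from files
#'
#' File-path front end used by the command-line script: reads FASTA, VCF and
#' BED inputs, runs [run_pipeline()], and writes the probe order, final SNP
#' list, funnel and spacing reports into `out_dir`.
#'
#' @param fasta,vcf_path,repeats_bed,sam_path input paths (`repeats_bed` and
#'   `sam_path` optional).
#' @param out_dir output directory.
#' @param ... passed to [run_pipeline()].
#' @return the `chip_design` object, invisibly.
#' @export
run_pipeline_files <- function(fasta, vcf_path, repeats_bed = NULL,
                               sam_path = NULL, out_dir = ".", ...) {
  genome <- read_fasta(fasta)
  vcf <- read_vcf(vcf_path)
  repeats <- if (!is.null(repeats_bed)) read_bed(repeats_bed) else interval_set()
  reads <- if (!is.null(sam_path)) read_sam(sam_path) else NULL
  res <- run_pipeline(genome, vcf, repeats, reads = reads, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_order(res$probes, file.path(out_dir, "probe_order.tsv"),
                    file.path(out_dir, "probe_oligos.fa"))
  write.table(res$thinned[, c("id", "contig", "pos0", "maf")],
              file.path(out_dir, "chip_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$funnel, file.path(out_dir, "funnel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(funnel = setNames(as.list(res$funnel$count),
                                    res$funnel$stage),
                  filter_tally = as.list(res$filter$tally),
                  screen_tally = as.list(res$screen$tally),
                  design_tally = as.list(res$design$tally),
                  spacing_fraction_15_70kb = res$spacing$fraction_in_band)
  if (!is.null(res$qc)) {
    summary$qc <- list(fractions = as.list(res$qc$fractions),
                       mean_target_depth = res$qc$mean_target_depth,
                       target_coverage = res$qc$target_coverage,
                       uniformity = as.list(res$qc$uniformity$fractions))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
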