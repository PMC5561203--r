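# baitforge

Design and evaluation of solution-hybrid-selection (SHS) target-enrichment
SNP chips, in R.

Capture-based genotyping reads a fixed SNP panel by hybridizing
biotinylated baits to the genomic fragments around each SNP and sequencing
the enriched library. Building such a panel from a cohort's variant calls
is a funnel, and `baitforge` implements every stage of it:

1. **Cohort filtering** — reduce a VCF to biallelic SNPs with the
   GATK-style hard filter
   `QD < 2.0 || FS > 60.0 || MQ < 40.0 || MQRankSum < -12.5 ||
   ReadPosRankSum < -8.0`, a total-depth window of [80, 1000], and
   missingness / low-depth-sample rules (plus optional MAF and
   Hardy–Weinberg screens).
2. **Flank screening** — each survivor's 150-bp flanks must form no
   hairpin with a stem longer than 8 bp, must be unique genome-wide
   (canonical 30-mer multiplicity), and the SNP must not sit in a repeat.
3. **Bait/probe design** — enumerate every 90-bp bait covering the SNP
   with its center within 50 bp, screen by GC content (30–70%) and
   hairpins, keep the two (or three) best placements — preferring centers
   about 20 bp off the SNP — and emit 120-mer synthesis oligos
   (`GAAGCGAGGATCAAC` + bait + `CATTGCGTGAACCGA`), with double synthesis
   copies for hairpin-rescued and dual-target probes.
4. **Density thinning** — score SNPs in consecutive 40-kb windows by

   ```
   Score = MAF * (E - S) * (1 - |a - (E-S)/2| / ((E-S)/2))
   ```

   (a triangular weight peaking at the window center, scaled by minor
   allele frequency) and keep the top scorer per window, with a whitelist
   for must-keep markers; report nearest-neighbor spacing statistics.
5. **Capture QC** — from alignments of a chip sequencing run: read
   filtering (>10% N, >40% bases ≤ Q10, adapter, duplicates), on-flank vs
   off-target base accounting against SNP ± 300 bp regions, per-offset
   depth profiles, coverage uniformity at 0.4×/0.8× of mean depth,
   GC-vs-depth tables, and cross-run SNP concordance.

A deterministic synthetic-data module (`make_genome()`,
`make_cohort_vcf()`, `make_capture_reads()`) generates genomes with
planted hairpins, duplications and repeats, cohort VCFs with planted
filter violations, and kernel-placed capture reads — with exact truth
tables, so the entire pipeline is testable offline. See the vignette
(`vignettes/chip-design-methods.Rmd`) for the methods in full.

## Worked example

```r
library(baitforge)
cfg <- synthetic_config(seed = 1)   # 200-SNP synthetic study, 73 animals
res <- run_synthetic_study(cfg)
res
#> chip_design funnel:
#>   input_sites  200
#>   post_filter  150
#>   post_screen  90
#>   post_design  90
#>   final_chip   10
#>   spacing in 15-70 kb: 100.0%
```

200 simulated sites lose the 50 planted hard-filter violations, then the
60 planted flank defects (30 hairpin, 20 non-unique, 10 in-repeat), all 90
clean SNPs obtain probes, and 40-kb thinning keeps one SNP per window —
every count matches the generator's truth table:

```r
res$screen
#> screen_result: 90 of 150 SNPs pass; rejections: EDGE 0, REPEAT 10,
#>   HAIRPIN 30, NON_UNIQUE 20
res$design
#> probe_design: 180 probes for 90 SNPs
#> designed=90, dropped_no_probe=0, dropped_one_probe=0, rescued=0,
#>   multi_snp_doubled=0
head(res$probes[, c("probe_id", "snp_id", "center_offset", "gc", "copies")], 2)
#>      probe_id  snp_id center_offset  gc copies
#> 11 snp0012_p1 snp0012           -20 0.5      1
#> 12 snp0012_p2 snp0012            20 0.47     1
```

Each designed SNP gets two baits bracketing it at ±20 bp. The simulated
capture run of the final panel then yields the standard enrichment
metrics — 87% of bases aligned, 56% on the ±300-bp flanking regions, ~40×
at the SNP bases, and sharply center-peaked coverage:

```r
res$qc
#> capture_qc_report
#>   total bases        133400
#>   aligned            87.0%
#>   uniquely aligned   77.7%
#>   on flanking region 56.3%
#>   off target         30.7%
#>   mean target depth  38.1X
#>   target coverage    100.0%
#>   uniformity >=0.4x 100.0%, >=0.8x 90.0%
```

Real inputs run through the same surface: `read_fasta()`, `read_vcf()`,
`read_bed()`, `read_sam()` feed `run_pipeline()` (or
`run_pipeline_files()`, which also writes the probe order TSV/FASTA and a
JSON summary). `inst/scripts/baitforge` wraps the same calls as a shell
command with `simulate`, `pipeline` and `qc` subcommands.

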