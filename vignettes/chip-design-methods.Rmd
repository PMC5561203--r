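---
title: "Designing and evaluating a capture-based SNP chip with baitforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a capture-based SNP chip with baitforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitforge)
```

## The problem

Solution hybrid selection (SHS) genotyping reads a fixed panel of SNPs by
capturing the genomic fragments around each SNP with biotinylated RNA baits
and sequencing the enriched library. Designing such a chip is a funnel: a
cohort's variant calls are reduced to well-behaved biallelic SNPs, each
survivor's flanking sequence is screened for features that would ruin
hybridization, capture baits are tiled over the remaining SNPs, and the
panel is thinned to a roughly even genomic spacing. After sequencing, a set
of standard capture metrics verifies that the enrichment actually worked.
`baitforge` implements every stage of that funnel plus the evaluation
metrics, and ships a deterministic simulator so the whole pipeline can be
exercised, with exactly known truth, on a laptop.

## Cohort filtering

`filter_cohort()` reduces a VCF to biallelic candidate SNPs. Four rules are
applied per site, all thresholds collected in `filter_thresholds()`:

* **Hard filter** — the GATK-style OR-expression
  `QD < 2.0 || FS > 60.0 || MQ < 40.0 || MQRankSum < -12.5 ||
  ReadPosRankSum < -8.0`. A clause only fires when its annotation is
  present; a missing key never fails a site, matching GATK
  `VariantFiltration` semantics. All comparisons are strict, so a site at
  exactly QD = 2.0 passes. The GWA-style variant of the expression
  (`QD < 4.0`, `HaplotypeScore > 13.0`) is reachable by overriding
  thresholds rather than by separate code.
* **Total depth** — INFO `DP` (or the sum of per-sample depths when absent)
  must lie in [80, 1000], bounds inclusive: the range is read as the
  acceptable interval, so its endpoints are acceptable.
* **Missingness** — a site is excluded when more than 20% of genotypes are
  missing, or when more than 20% of individuals have depth below 2. These
  two triggers are combined as an OR by default: an exclusion list that
  names two criteria conventionally means either suffices. The literal
  conjunctive reading is available as `missingness_mode = "both"`.
* **MAF / HWE** — generic cohort screens (folded MAF minimum; 1-df
  chi-square Hardy–Weinberg test without continuity correction,
  monomorphic sites conventionally p = 1). Both are off by default because
  chip design weights MAF later, in the ranking score, rather than
  thresholding it early; genome-wide association QC would enable them
  (e.g. `hwe_p_min = 0.001`).

Each failed site is tallied under its highest-priority reason
(`NOT_BIALLELIC` → `HARD_FILTER` → depth → missingness → MAF → HWE), so the
tally plus survivors always reconstructs the input count — that conservation
is asserted in the tests.

## Flank screening

A candidate SNP's two 150-bp flanks (the SNP base itself excluded) must
satisfy three screens, applied by `screen_candidates()`:

* **No hairpin** (`detect_hairpin()`): no two non-overlapping exact
  reverse-complement arms of ≥ 9 bp separated by ≥ 3 intervening bases.
  The 9-bp minimum stem encodes "longer than 8 bp is harmful": 8-bp stems
  pass. The model is deliberately combinatorial — exact complementarity, no
  mismatches, bulges or free-energy terms — because the screen's purpose is
  a conservative, deterministic rejection rule, not a folding prediction.
  The loop minimum of 3 nt is the shortest loop a DNA stem-loop can
  physically close. N matches no base anywhere in the package.
* **Genome uniqueness** (`kmer_uniqueness()`): every flank is decomposed
  into canonical (strand-collapsed) 30-mers and looked up in a genome-wide
  multiplicity index; a flank is unique when at least 95% of its 30-mers
  occur exactly once. This is a self-contained stand-in for an
  alignment-based mappability screen: k = 30 makes random 30-mer collisions
  vanishingly rare even in mammalian-scale genomes, while verbatim
  duplications of any appreciable length drive the fraction to zero. Both
  k and the 0.95 cutoff are configurable.
* **No repeat overlap** (`repeat_overlap()`): the SNP position itself (a
  point, half-open convention) must not fall inside the supplied repeat
  annotation. Producing that annotation (e.g. RepeatMasker) is external.

Flanks truncated by a contig edge are screened out unconditionally.

## Bait and probe design

A probe is a synthesizable 120-mer: a 90-bp genome-matching bait between
two fixed 15-bp PCR arms (`GAAGCGAGGATCAAC` … `CATTGCGTGAACCGA`), assembled
by `build_oligo()`. For each SNP, `enumerate_baits()` tries every bait
placement that covers the SNP — 90 of them away from contig edges, all with
bait center within 45 bp of the SNP, inside the 50-bp placement limit. A
placement is viable when its GC fraction lies in [0.30, 0.70] (inclusive),
it contains no N, and it folds no ≥ 9-bp hairpin.

`select_probes()` keeps the best `n_select` (default 2) viable baits,
ranked by closeness of |center offset| to 20 bp — baits deliberately sit
slightly off-center so that a pair brackets the SNP — with ties broken by
GC closeness to 50% and then leftmost start, making selection total and
deterministic. SNPs with fewer than two viable placements are dropped, with
one rescue: when exactly two placements pass GC and placement and exactly
one of them is hairpin-flagged, the clean one is kept at double synthesis
copies. Probes whose bait covers two or more panel SNPs are likewise
doubled, since they serve two targets. Probes are designed on the forward
strand only (capture hybridization is strand-agnostic); a both-strand mode
was considered and rejected as doubling synthesis cost for no capture gain.

## Density thinning

Chips aim for even genome coverage. `assign_windows()` tiles each contig
with non-overlapping 40-kb windows anchored at coordinate 0 (terminal
windows keep their true width), and each SNP gets the ranking score

$$\mathrm{Score} = \mathrm{MAF} \cdot (E-S) \cdot
  \left(1 - \frac{|a - (E-S)/2|}{(E-S)/2}\right)$$

where $S, E$ bound the window and $a$ is the SNP's offset from $S$. The
weight is triangular — 1 at the window center, 0 at the edges — so the
score prefers common, centrally placed SNPs; its maximum is
$\mathrm{MAF}\cdot(E-S)$. The offset interpretation $a = \mathrm{pos} - S$
is the only reading under which the weight spans [0, 1].
`thin_windows()` keeps the top scorer per window (ties: nearer the center,
then lower coordinate; the cap is configurable rather than gated on a
density trigger, which subsumes both "thin dense regions" and "keep sparse
regions" behaviours). A whitelist of must-keep SNPs — e.g. trait-associated
markers added from outside the cohort — bypasses thinning and is
deduplicated by position. `spacing_stats()` then reports nearest-neighbor
distances and the fraction inside 15–70 kb, the band used to judge evenness
around the 40-kb design target.

## Capture QC

`capture_qc_report()` evaluates a sequencing run of the finished chip
against the panel (targets = SNP ± 300 bp):

* read filtering: drop reads with > 10% N bases, > 40% bases at quality
  ≤ 10, adapter contamination, or the SAM duplicate flag;
* base accounting: total / aligned / uniquely aligned (MAPQ ≥ 30) /
  on-flank / off-target bases. A read overlapping a target region by one
  base credits all its bases on-flank, because capture reports tabulate
  megabases by read class; a per-base intersection mode is a flag away.
  On-flank and off-target always partition aligned bases exactly;
* `depth_profile()`: mean depth at each offset −300…+300 from the SNP,
  the unimodal center-weighted signature of successful enrichment;
* per-target depth (at the SNP base itself; region-mean by flag),
  coverage at a depth threshold, and `coverage_uniformity()` — fractions
  of targets at ≥ 0.4× and ≥ 0.8× of mean depth;
* `gc_depth_table()`: mean depth by region-GC bin (default bins split at
  30/50/70% GC), exposing GC capture bias;
* `snp_concordance()`: shared-site fractions between two call sets keyed
  by (contig, position, alt), for cross-platform comparisons.

## The synthetic study

`synthetic_config()` fixes the simulated study; every generator is fully
determined by `(config, seed)` and regenerating gives byte-identical
FASTA/VCF/BED/SAM output. The defaults encode the study design this
package targets, at desk scale:

* a 400-kb design contig carrying 200 SNP loci, a 73-individual cohort,
  per-sample Poisson(8) depths and 5% genotype missingness;
* planted defects with disjoint, recorded fates: 30 hairpin flanks, 20
  flanks duplicated verbatim onto a separate duplication-bank contig, 10
  SNPs inside repeat annotations, and 10 sites violating each of the five
  hard-filter clauses (the clause's own annotation drawn from a violating
  range, everything else from comfortably passing ranges);
* capture reads: 50-bp single-end, 56% placed on targets via a Gaussian
  kernel (s.d. 75 bp) centered on the target SNP, 13% unmapped, the rest
  uniform background; 10% of mapped reads at MAPQ 0; 2% PCR duplicates,
  1% N-rich and 1% low-quality reads planted. 153 on-target reads per
  target put the SNP-base depth near 40×, and the kernel makes coverage
  negligible beyond ~200 bp — the depth-profile shape a working capture
  shows.

Exactness matters more than realism here: each SNP neighbourhood is
rejection-sampled until both flanks are clean of *incidental* hairpins
before its designated defect is planted, so every screen tally is an exact
integer match to the truth table, not a statistical one. (Incidental 9-bp
stems arise in ~4% of random 150-mers, which would otherwise contaminate
the counts.) Duplication copies are recorded in the repeat annotation at
the copy location only, so the source SNPs exercise the uniqueness screen
rather than the repeat screen.

What the simulator does **not** emulate: sequencing errors and quality
decay, indels, paired-end structure, realistic repeat families and GC
heterogeneity, linkage disequilibrium between sites, and population
structure. Green tests therefore demonstrate the pipeline's logic —
filters, screens, selection, thinning, accounting — not robustness to raw
real-world data, which additionally depends on the upstream aligner and
caller.

## Numerical and scale choices

Problem sizes were chosen so the full test suite runs in a couple of
minutes: the shared unit fixture uses 60 SNPs on 150 kb; the planted-truth
funnel uses the default 200 SNPs on 400 kb; the thinning oracle check uses
10,000 SNPs over 10 Mb; capture recovery uses 50 targets on 2 Mb
(~13,600 reads), where the target footprint (1.5% of the genome) keeps the
background's contribution to the on-flank fraction well under the 2%
recovery tolerance. The k-mer index counts canonical k-mers in a hash
table; lookups are exact, and absent k-mers count as non-unique (they
cannot be confirmed unique against the reference). Ties anywhere in
selection and thinning are broken by fixed deterministic keys, so reruns
are byte-identical. All internal coordinates are 0-based half-open, with
1-based coordinates only at the VCF boundary.

## A worked run

```{r, eval = FALSE}
cfg <- synthetic_config(seed = 1)
res <- run_synthetic_study(cfg)
res$funnel
res$qc
```

Known limitations: hairpin screening ignores thermodynamics; uniqueness is
k-mer-based, not alignment-based; SAM parsing covers the headered text
subset the QC needs (no BAM/CRAM); thinning is not linkage-aware; and the
probe-library split into synthesis sub-libraries is a round-robin
convenience without biological meaning.
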