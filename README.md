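# splicemod

Quantitative machinery for studying small-molecule splicing modifiers — the
compound class that corrects *SMN2* exon 7 skipping in spinal muscular
atrophy — from both ends of their mechanism:

* **Transcript side.** A catalog of *local* alternative-splicing events is
  built from transcript annotations (cassette exons, alternative 3′/5′
  splice sites, paired and multi-exon cassettes, mutually exclusive exons),
  and each event is quantified from spliced read alignments with a
  percent-spliced-in score. Writing `c1` and `c2` for the counts of reads
  unique to each alternative, normalized by the length of the unique
  sequence stretch,

  ```
  PSI = c1 / (c1 + c2),          ΔPSI = mean PSI(treated) − mean PSI(control)
  ```

  Events are retained when the normalized read density of at least one
  variant reaches 0.003 reads/nt, and changes are flagged at |ΔPSI| > 0.4.

* **Protein side.** Affinity-proteomics statistics for compound pulldowns:
  a SILAC enrichment filter chain (≥ 2 quantified peptides, search score
  > 31, detection in ≥ 7/10 samples, best gel band per protein), label-swap
  harmonization, one-sided tests of mean log2 ratio > 0 with
  Benjamini–Hochberg adjustment and a 1.5-fold cutoff; Fisher
  category enrichment with a ribosomal-exclusion re-run; and a
  dose-dependent **displacement test** for RNA-bait pulldowns under rising
  free-compound concentration: an empirical-Bayes moderated one-way fit,
  monotonic above/below-cut contrasts across the ordered doses, a
  per-protein max-*t* statistic, and Westfall–Young step-down minP
  permutation p-values (1000 label permutations, one-sided), with binders
  called at adjusted p < 0.05.

A synthetic-data module generates every input with known ground truth —
gene models covering all six event classes (including a cassette exon
carrying the ESE2 enhancer `AAAAAGAAGGAAGG`), paired-end 2×50 spliced reads
at specified PSI, SILAC ratio tables with spiked enriched proteins, and
5-concentration × 3-replicate dose-response matrices with spiked displaced
proteins — so the full pipeline is testable end to end without any external
data.

The package is aimed at computational biologists building or validating
splicing-modifier screens; everything is plain R with Bioconductor
infrastructure (rtracklayer, Rsamtools, GenomicAlignments) for standard
formats.

## Worked example

```r
library(splicemod)

# simulate a cassette-exon gene and spliced reads at PSI 0.7
tr  <- gen_transcriptome(11, events_per_category = c(CASSETTE = 1),
                         ese2_fixture = FALSE)
cat_ <- build_event_catalog(tr$transcripts, read_len = 50, min_overhang = 1)
cat_$table[, c("category", "unique_length1", "unique_length2")]
#>   category unique_length1 unique_length2
#> 1 CASSETTE            148             49

rd <- gen_reads(tr$transcripts, psi = setNames(0.7, "G001"),
                depth = 2000, seed = 1)
quantify_event(cat_$events[[1]], cat_$unique_regions[[1]], rd$alignments)
#>    n1 n2       c1       c2    psi
#>   443 54 2.993243 1.102041 0.7309
```

`unique_length2 = 49` is the skipping alternative's single junction at
50-nt reads with a 1-nt overhang (50 − 2·1 + 1); the inclusion alternative
adds two junctions plus the in-exon start positions. PSI estimates at depth
2000 land within ±0.05 of truth (mean absolute error ≈ 0.02).

The numbered scripts under `analysis/` run the whole study on simulated
data — `01_simulate_data.R` through `05_assay_stats.R` — writing tables
under `results/`. On the shipped seeds the pipeline recovers 13/13 seeded
events with 0 spurious ones, flags exactly the one cassette event shifted
by ΔPSI = 0.49 (0.69 vs 0.20), calls 25/25 spiked SILAC proteins with no
false positives, and finds all 10 displaced proteins at step-down minP
p = 1/1001 with no false binders.

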