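---
title: "Methods: local splicing-event quantification and splicing-modifier proteomics statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local splicing-event quantification and splicing-modifier proteomics statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemod)
```

# Scope and scientific setting

Small-molecule splicing modifiers of the SMN-C class promote inclusion of
*SMN2* exon 7 with remarkable gene selectivity. Characterising such
compounds needs two complementary quantitative pipelines: a
transcript-side pipeline that measures how splicing outcomes shift under
treatment, and a protein-side pipeline that identifies which proteins the
compound binds or displaces at RNA elements such as the purine-rich ESE2
enhancer (`5'-AAAAAGAAGGAAGG-3'`) in exon 7. `splicemod` implements both,
plus the small closed-form assay statistics (efficiency-based qPCR
abundance, 2^-ddCt enrichment, SPR percent binding) that support them, and
a synthetic-data module that generates every input with known ground
truth. All empirical statements in this document are recomputed by the
test suite or by `scripts/acceptance.R`.

# Local splicing events and PSI

## Event model

Short reads cannot identify full-length isoforms, so splicing is
quantified as *local* events: bounded differences between two transcript
isoforms flanked by shared splice sites. Six categories are distinguished:
single-exon (`CASSETTE`), two-exon (`LCASSETTE`) and three-or-more-exon
(`XCASSETTE`) inclusion/skipping, alternative 3' acceptor (`INTERNAL3`)
and 5' donor (`INTERNAL5`) length polymorphisms, and mutually exclusive
exon pairs (`MUT_EXCLU`).

Internally all coordinates are 0-based half-open on the genome axis; GTF
input (1-based closed) is converted at the boundary, which keeps junction
arithmetic free of off-by-one cases. Event extraction compares every
transcript pair of a gene with a merge walk that anchors on identical
exons (first/last exons anchor flexibly on their internal splice site
only, since alternative transcription start/polyadenylation sites are not
part of the taxonomy). Each maximal difference region between shared
anchors is matched against the six templates; anything else — nested or
overlapping alternatives, regions touching a transcript end — is labelled
`OTHER` and excluded from PSI analysis. Events are deduplicated across
pairs by a canonical key (gene, category, flank coordinates, exon-chain
coordinates of both alternatives), which makes the catalog invariant to
transcript input order.

## Unique evidence and PSI

For each alternative we collect the evidence only it can produce: its
specific splice junctions and the exonic segments absent from the other
alternative. With read length $L$ and minimum junction overhang $m$
(defaults 50 and 1, matching 2×50 bp paired-end sequencing), a junction
offers $L - 2m + 1$ distinct read-start positions and an exclusive segment
of length $\ell$ offers $\max(\ell - L + 1, 0)$ fully-contained positions;
their sum is the alternative's *unique length*. A read supports an
alternative if it spans one of its specific junctions with at least $m$
aligned nt on both sides, or lies fully inside one of its exclusive
segments; reads whose start or end sits exactly on a splice-site boundary
never span it. Raw counts are normalized by unique length,
$c_i = n_i/u_i$, and

$$\mathrm{PSI} = \frac{c_1}{c_1 + c_2} \in [0, 1],$$

with alternative 1 the inclusion-type (larger exonic content)
alternative. When both counts are zero the PSI is missing — never coerced
to 0 or 0.5, so low coverage cannot fabricate signal. The boundary case
$L = 2m$ is allowed and leaves exactly one valid start position per
junction.

Paired-end fragments are counted mate-wise; a fragment whose two mates
support *different* alternatives is internally inconsistent and is
discarded entirely. Events are retained when any variant in any sample
reaches a normalized density of 0.003 reads/nt; the threshold is applied
per sample because the replicate structure should not dilute a
well-covered sample. ΔPSI is the difference of per-condition means of
per-sample PSI values (missing values dropped from the means, not
imputed), flagged at |ΔPSI| > 0.4. Averaging per-sample PSI rather than
pooling counts across replicates weights replicates equally regardless of
depth; with the balanced designs simulated here the two estimators are
nearly identical.

# Synthetic data: what it emulates, and what not

`gen_transcriptome()` realizes each requested event as a two-isoform gene
with exon lengths 80–300 nt and elementary introns 100–2000 nt, padded
with three constitutive flanking exons per side so that both isoforms are
several-fold longer than the sequencing fragments — as local events inside
real multi-exon genes are. Without that padding a skipping isoform can be
shorter than the fragment length, fragments then pin to the transcript
ends and junction coverage collapses; the padding is therefore structural
realism, not a tuning knob. Strands are drawn at random and minus-strand
genes are built by mirroring the plus-strand geometry, which preserves the
event category by construction. One extra cassette gene carries the ESE2
motif in its cassette exon for motif-level fixtures.

`gen_reads()` draws, per fragment, an isoform and a uniform position on
it; fragment lengths are normal(250, 30) truncated to the feasible range,
and 2×50 nt mates are emitted as spliced alignments (M/N CIGAR) — the
aligner itself is out of scope, so reads are born aligned. The `psi`
parameter is interpreted as the *molar* fraction of the inclusion isoform,
which is what the length-normalized PSI estimator measures: the
fragment-level inclusion probability is
$p_1 = \psi \tilde L_1 / (\psi \tilde L_1 + (1 - \psi) \tilde L_2)$ with
$\tilde L = \max(L - 250 + 1, 1)$ the effective length. A literal
"fragment with probability psi" generator (`length_weighted = FALSE`,
kept for the binomial sanity checks) would make the PSI estimator
converge to a length-distorted value whenever the isoforms differ in
length, and no consistent estimator of that quantity exists from
length-normalized counts alone. The generators do not model sequencing
errors, base qualities, PCR duplicates, multi-mapping or overdispersed
coverage; passing tests therefore demonstrate correctness of the
quantification logic under idealized coverage, not robustness to aligner
artefacts.

`gen_silac()` emits a 10-sample table (samples 6–10 label-swapped, i.e.
ratios inverted) with per-sample log2 noise sd 0.3, 5% missingness
completely at random, and spiked enriched proteins at mean log2 ratio 2 —
the regime of a strong RNase-sensitive pulldown enrichment. Decoy rows
(single-peptide, sub-threshold score, sparse detection, duplicate
lower-abundance band) exercise every branch of the filter chain.
`gen_dose_response()` emits a 5-level (0, 0.5, 1, 5, 10 µM) × 3-replicate
matrix; displaced proteins decrease by `drop_per_level` (default 2·sd,
sd = 0.25) per ordered level step. With $K$ levels there are $K-1$ steps,
so the total drop is $(K-1)\cdot$`drop_per_level`.

Every generator is a pure function of (seed, parameters): identical calls
give byte-identical files, and the caller's RNG state is saved and
restored.

# SILAC enrichment statistics

Rows are filtered exactly as a Mascot-quantified pulldown table would be:
at least two quantified peptides, score strictly above 31, a non-missing
ratio in at least 7 of 10 samples, and — where one protein was identified
in several gel bands — only the band with the highest abundance (total
intensity, or peptide count when no intensity is available). Label-swapped
samples' linear ratios are inverted before the log2 transform;
non-positive ratios are set missing with a warning rather than silently
propagating `NaN`.

Per protein, a one-sample one-sided t-test of mean log2 ratio = 0 against
"> 0" (enrichment with the active ligand) is computed, with
Benjamini–Hochberg adjustment across proteins. The enrichment call
requires both adjusted p ≤ 0.05 and a fold-change criterion. Two readings
of the 1.5-fold rule circulate in this literature — linear ratio > 1.5
(i.e. mean log2 > log2 1.5 ≈ 0.585) and log2 fold change > 1.5; the
package defaults to the linear reading, which corresponds to the
operational "ratio between groups > 1:1.5" formulation, and exposes
`fold_scale = "log2"` for the stricter one. A protein with zero spread and
zero mean gets t = 0, p = 0.5 by convention; fewer than two quantified
ratios yield a missing p and never an enrichment call.

Category enrichment is a one-sided Fisher exact test per annotation
category on the (hit / non-hit) × (in / out of category) table over the
tested universe, reported as −log10 p with a 0.001 call threshold. The
`exclude` argument re-derives hits and background without a protein set
(e.g. all ribosomal proteins) before testing, reproducing the style of
exclusion re-analysis used to show that an enrichment is not driven by
the translational machinery.

# Dose-response displacement test

For an RNA-bait pulldown under increasing free-compound concentration,
specific binders are displaced: abundance decreases monotonically in
dose. The test statistic is built in four stages.

1. **Moderated fit.** A one-way group-mean fit per protein across the
   ordered concentration levels gives residual variance $s^2$ with $d$
   degrees of freedom. A scaled inverse chi-square prior with parameters
   $(d_0, s_0^2)$ is estimated across proteins by matching the mean and
   variance of $\log s^2$ (corrected by digamma/trigamma terms for the
   chi-square log-bias); the posterior variance is
   $s^2_{\mathrm{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$. The estimator is
   implemented in the package and agrees with the established
   empirical-Bayes implementation (`limma::fitFDist`) to numerical
   precision on sampled data; tests verify both that agreement and
   parameter recovery (d0 within ±50%, s0² within ±20% at d0 = 4,
   s0² = 0.04, 500 proteins). Two degenerate corners are handled
   explicitly: exactly identical variances collapse the prior onto the
   common value (infinite d0), and exactly-zero variances are excluded
   from prior estimation since their logarithm carries no scale
   information.

2. **Monotonic contrasts.** For each cut between consecutive levels
   $k = 1..K-1$, a two-group moderated t compares the samples at or below
   the cut with those above:
   $t_k = (\bar y_{\le k} - \bar y_{> k}) / \sqrt{s^2_{\mathrm{post}}
   (1/n_{\mathrm{lo}} + 1/n_{\mathrm{hi}})}$, positive when abundance
   falls with dose. Sample-weighted (pooled) means are used on each side.

3. **Max-t.** The per-protein statistic is the signed maximum over cuts —
   sensitive to a decrease at any dose threshold, and never clipped at
   zero.

4. **Step-down minP.** Concentration labels are permuted across all
   samples (B = 1000 by default) and the *entire* pipeline, variance
   moderation included, is recomputed per permutation, keeping the null
   distribution faithful to the data-dependent moderation (a
   `refit_moderation = FALSE` switch freezes the observed prior instead).
   Raw per-protein p-values use each protein's own permutation null with
   add-one smoothing, $p = (1 + \#\{T^{(b)} \ge T_{\mathrm{obs}}\})/(B+1)$,
   which is exactly the convention of including the identity permutation
   in the null set and guarantees $p \ge 1/(B+1)$. Family-wise adjustment
   follows the single-pass Westfall–Young step-down minP construction
   over the shared permutations: per-permutation p-values from row-wise
   ranks (ties resolved by the ≥ comparison), successive minima taken
   from the least significant end along the raw-p ordering (ties broken
   by descending observed t), adjusted p-values counted with the same
   smoothing, and monotonicity enforced by a cumulative maximum. For
   small designs `exhaustive = TRUE` enumerates all distinct label
   assignments instead, and the tests verify exact equality with an
   independent loop-based enumeration oracle built on limma's moderation.

Binders are proteins with adjusted p strictly below 0.05. The procedure
that pairs a permutation minP step with a subsequent BH pass appears in
this literature with the order underspecified; since step-down minP is
already a multiplicity adjustment (FWER), the package reports it as the
default adjusted p and exposes `adjust = "bh"` (BH on the raw permutation
p-values, FDR-style) and `adjust = "minp_bh"` (a literal further BH pass)
rather than guessing one chaining as intended. Proteins missing all
observations at any level are reported untested (`NA`) rather than tested
on a partial design.

# Assay closed forms

qPCR abundance uses actual amplification efficiencies,
$A = E^{-C_t}$ with $E \in (1, 2]$ per target (default 2); fold changes
normalize first to the reference gene within sample, then to the mean of
the vehicle (DMSO) control samples. Pulldown enrichment uses
$2^{-\Delta\Delta C_t}$. SPR percent binding normalizes the observed
response to the theoretical maximum for 1:1 stoichiometry,
$R_{\max} = R_{\mathrm{immobilized}} \cdot M_{\mathrm{analyte}} /
M_{\mathrm{ligand}} \cdot n_{\mathrm{sites}}$, so 100% is full occupancy
of one site. All three are pure closed forms tested against hand
computations to 1e-12.

# Problem sizes and numerical choices

The shipped analyses and tests use: event-catalog round trips on 12–13
two-isoform genes (2 per category); PSI recovery at depth 2000 fragments
with 5 replicates per level and 100 Monte-Carlo runs for the ΔPSI flag
rate; SILAC recovery at 500 proteins / 25 enriched (effect 2, sd 0.3)
over 25–50 seeds; displacement null-error and power at 200 proteins,
B = 1000 permutations, over 5–20 seeds. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the property margins (e.g.
binomial sd ≈ 0.01 on a 0.95 sensitivity bound) while keeping each
analysis in the seconds-to-minutes range on one core.

Further numerical conventions: junction keys are packed into doubles
(exact below 2^53) for vectorized matching; permutation comparisons use ≥
throughout so that exact ties count conservatively toward the null;
sub-seeds derived in scripts stay below 2^31 (R's integer range); and
deterministic tie-breaks (score, then band; raw p, then observed t) make
every output invariant to input row order.

# Known limitations

* Overlapping or >2-way splicing alternatives are not decomposed; they
  surface as `OTHER` and are excluded from PSI, so complex loci are
  under-reported rather than mis-reported.
* Terminal-exon alternatives (alternative TSS/polyA, terminal acceptor or
  donor shifts) are outside the six-class taxonomy and are ignored.
* Multi-mapping reads are assumed resolved upstream by the aligner.
* The displacement test's monotone alternative trades power against
  non-monotone (e.g. hook-shaped) dose responses for sensitivity to the
  displacement signature; IC50/EC50 curve fitting is out of scope.
* Synthetic proteomics tables model noise as Gaussian on the log scale
  with MCAR missingness; intensity-dependent missingness and peptide-level
  interference are not emulated.
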