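---
title: "QTL-seq bulked-segregant analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The problem and the statistic

Bulked-segregant analysis by sequencing (QTL-seq) localizes a quantitative
trait locus by pooling the two phenotypic extremes of a segregating
population and sequencing the pools. The motivating design is the
*Brassica napus* seed-colour experiment: 188 recombinant inbred lines
(RILs, F~2:11~) from the yellow-seeded GH06 x black-seeded ZY821 cross,
with 25 yellow-seeded and 25 black-seeded lines pooled into two bulks and
sequenced to roughly 40x, aligned against the black parent's genome.

At a site where the parents are fixed for different alleles, the
**SNP-index** of a bulk is the fraction of its reads carrying the ALT
(yellow-parent) allele,

$$\mathrm{SI}_b = \frac{\text{ALT reads}_b}{\text{ALT reads}_b + \text{REF reads}_b},$$

and the scan statistic is
$\Delta\mathrm{SI} = \mathrm{SI}_{\text{high}} - \mathrm{SI}_{\text{low}}$.
At loci unlinked to the trait both bulks are random draws from the
population and $\Delta\mathrm{SI}$ fluctuates around 0; at a causal locus
the bulks are enriched for opposite alleles and $\Delta\mathrm{SI}$
approaches +1 (the black parent is the reference, so the causal signal is
positive by construction). Sites are averaged in 1-Mbp windows advanced in
10-kbp steps; windows with fewer than 10 SNPs are skipped, and window
means are unweighted.

## Filtering

Two per-record predicates produce the analysis-ready SNP set (composition
is order-independent):

* **Site-quality hard filter**: remove records with QD < 2.0, FS > 60.0,
  MQ < 20.0, MQRankSum < -12.5 or ReadPosRankSum < -8.0. Inequalities are
  strict, so boundary values pass; annotations absent from INFO never cause
  removal (callers omit rank-sum statistics at homozygous-only sites, and
  absence is not evidence of an artifact).
* **Bulk-genotyping criteria**: per-sample depth >= 5 in both parents and
  both bulks (DP when present, else the sum of allele depths); parents
  homozygous for different alleles; and the reference-role parent
  homozygous-REF (its genome is the alignment target, so any other call is
  an alignment or calling error).

Multi-allelic records are dropped globally: the SNP-index is defined for a
single ALT allele and the design is biparental.

## The null band

Per-window confidence cutoffs come from a two-stage binomial Monte Carlo
under the null hypothesis of no QTL, conditioned on the observed read
depths. For each replicate, each bulk draws the number of ALT-carrying
lines among its $k$ pooled RILs as $\mathrm{Binomial}(k, 1/2)$ — lines are
treated as homozygous, since residual heterozygosity at F~2:11~ is
$(1/2)^{10} \approx 10^{-3}$ — and each member site then draws ALT reads
as $\mathrm{Binomial}(\text{depth}, \text{count}/k)$. Cutoffs at the 95%
and 99% levels are nearest-rank empirical percentiles of the absolute
window-mean $\Delta\mathrm{SI}$ (the band is symmetric); region calling
defaults to positive exceedance of the 99% cutoff, with a two-sided
option. The default replicate count is 100{,}000; examples and tests use
fewer.

The one genuinely open modelling question is how the line draw relates to
the sites *within* a window, and `simulate_null_band(site_linkage = )`
exposes both answers:

* `"complete"` (default): one line configuration per bulk per replicate,
  shared by every member site. A 1-Mbp window spans only ~2 cM on a
  *B. napus*-scale map, so across the 50 pooled lines its sites segregate
  essentially as one block (origin correlation > 0.9 between window ends).
  In this limit the window mean inherits the single-site line-sampling
  variance $2 \times \tfrac{1}{4k}$ plus averaged read noise, which at
  $k = 25$ and ~40x depth puts the 99% cutoff near 0.36–0.45 — the scale
  the seed-colour scan's reported peak-difference values imply.
* `"independent"`: a fresh line configuration per site, appropriate only
  when member sites are effectively unlinked. For an $m$-SNP window this
  shrinks the cutoff by roughly $\sqrt{m}$, which badly under-covers on
  linked data; it is retained because it is the natural model for sparse
  or pruned marker sets and because the two models coincide exactly for
  single-SNP windows, where both are validated against a high-replicate
  oracle.

Windows sharing a depth multiset reuse one set of draws (the null depends
on the depths only). Consecutive significant windows merge into candidate
regions; skipped low-SNP windows do not break a run, because sparse
stretches inside a QTL region should not split it. Each region reports the
peak window's mean $\Delta\mathrm{SI}$, its 99% cutoff, and their
difference (the "peak difference value" of the published region tables).

## The simulator

`simulate_qtlseq_experiment()` generates data with exactly the structure
the statistics assume, so every stage is testable without external data:

* **Meiosis**: Haldane model — crossover count
  $\sim \mathrm{Poisson}(L\ \text{Morgans})$, positions uniform, no
  interference; physical and genetic coordinates related linearly. An F1
  carries one intact haplotype per parent; each of 10 selfing rounds
  (F~2:11~, read as 10 rounds after the F1 — the notation is defined
  nowhere, so this is stated explicitly) draws two independent gametes
  from the current plant. Residual heterozygosity then decays as
  $(1/2)^g$, and two loci $d$ Morgans apart are recombinant in a fraction
  $R = 2r/(1+2r)$ of lines with $r = \tfrac12(1-e^{-2d})$ — both checked
  against 50,000-line simulations.
* **Trait**: $y = \sum_i a_i g_i + e$, $g_i \in \{-1, 0, +1\}$ the centred
  yellow-dosage at QTL $i$, $e \sim N(0, \sigma_e^2)$. Effects can be
  sized from a target variance-explained fraction
  ($a = \sigma_e\sqrt{v/(1-v)}$, using genotypic variance ~1 at a
  segregating RIL locus); the motivating locus explains ~45% of trait
  variance. No epistasis or maternal effects are modelled.
* **Bulks**: the $k$ largest and $k$ smallest trait values (default 25
  each), ties broken deterministically by line identifier.
* **Reads**: per site and sample, depth $\sim$ Poisson (defaults 44x/41x
  for the bulks, 30x parents), ALT reads binomial with symmetric
  per-read error $\varepsilon$ (default 0.002, a post-filter Illumina
  scale); equal-weight pooling of lines is assumed. The black parent is
  REF at every site. Site annotations are drawn from disjoint
  clean/artifact ranges so a planted artifact fraction is exactly
  recoverable by the hard filters — the artifact mixture emulates filter
  behaviour, not caller physics.
* **Reproducibility**: one root seed; child streams per stage
  (population, trait, reads), so identical configurations give
  byte-identical VCFs.

What passing simulation tests does *not* show: robustness to real
alignment artifacts (the artifact sites here are caricatures in disjoint
ranges), to unequal line pooling, to segregation distortion, or to
non-uniform recombination (the linear bp–cM map has no pericentromeric
suppression). Those affect real scans and are outside the generator.

## Variant annotation

Gene models come from GFF3 (one canonical transcript per gene, the
longest CDS, so each variant gets one call). Context precedence when a
position matches several features is CDS > UTR > intron > upstream >
downstream > intergenic, with upstream/downstream the strand-aware 1-kb
flanks beyond the TSS/TTS, inclusive of the 1000th base. SNP effects
reconstruct the affected codon from the spliced CDS in transcript
orientation and use the standard nuclear code (stop-gain/loss reported
separately from other nonsynonymous changes); indel effects are
frameshift when length mod 3 is non-zero, and indels spanning a CDS
boundary are not classified (no published rule to follow). Effect calls
are property-tested against full-ORF re-translation on random synthetic
genes, on both strands.

## Segregation and interval utilities

`chi_square_gof()` is the plain $\sum (O-E)^2/E$ statistic against a
Mendelian ratio (scale-invariant in the ratio; Yates correction available
for two classes but off by default, as nothing indicates it was used);
`interval_width()` and `marker_map_summary()` do the fine-mapping
arithmetic, with mean adjacent marker spacing defined as span/(n-1). The
published segregation chi-square values for the 1:3 tests are not
reproduced by either the plain or the corrected statistic, so no attempt
is made to match them.

## Numerical conventions

* Coordinates 1-based inclusive (GFF3/VCF convention); windows anchored
  at base 1, membership half-open $[a, a+W)$.
* Percentiles are nearest-rank order statistics (`quantile type 1`):
  at 100,000 replicates the rounding is visible in the third decimal, so
  the definition matters for reproducibility.
* Mbp reported to 2 decimals in region tables; bp retained internally.
* Depths at ~10x give $\Delta\mathrm{SI}$ a coarse lattice (steps of
  1/depth); oracle comparisons of extreme percentiles are made at ~40x
  where the support is fine.

## Problem sizes used in the tests

The shipped checks run on deliberately small genomes: null-band
calibration uses 20 replicate null genomes of 10 x 4-Mbp chromosomes
(2,000 sites each, 10,000-replicate bands); power uses 40 replicate
pipelines on 3 x 20-Mbp chromosomes with one QTL at 45% variance
explained (2,000-replicate bands); simulator fidelity uses 50,000 lines.
These sizes give Monte-Carlo errors small enough for the stated bounds
while keeping a full run in minutes; all scale linearly if you wish to
tighten them.

## A worked example

```{r example, fig.width = 7, fig.height = 5}
gm <- scatter_marker_sites(
  genetic_map(data.frame(name = c("A09", "C03"),
                         length_bp = c(8e6, 6e6),
                         length_cm = c(16, 12))),
  c(800, 600))
cfg <- sim_config(n_lines = 188, bulk_size = 25, seed = 11,
                  artifact_fraction = 0.05)
vcf <- tempfile(fileext = ".vcf")
sim <- simulate_qtlseq_experiment(
  gm, cfg, qtl_effect("A09", 4e6, variance_explained = 0.45),
  env_sd = 1, vcf = vcf)

v <- read_bulk_variants(vcf)
filt <- filter_variants(v)
filt$summary

scan <- qtlseq_scan(filt$variants, window = 1e6, step = 2.5e5,
                    min_snps = 10, bulk_size = 25, n_rep = 2000, seed = 3)
summary(scan)
plot(scan)
```

The called region on A09 contains the planted locus at 4 Mbp, and its
peak $\Delta$(SNP-index) sits well above the green 99% band, while C03
stays inside the bands.

## Known limitations

* The null band conditions on observed depths but not on observed marker
  spacing; windows much wider in genetic distance than ~5 cM sit between
  the two `site_linkage` limits.
* One canonical transcript per gene means effects on minor isoforms are
  not reported.
* The simulator draws crossovers without interference; interference
  shortens real recombination tracts and slightly sharpens real scans
  relative to simulated ones.
* No LOD-based interval mapping, linkage-map estimation, or structural
  variant handling — the package scans pooled allele frequencies only.
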