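---
title: "Detecting TE insertions and comparing their population genetics across mating systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE insertions and comparing their population genetics across mating systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepop)
```

## Scope and model

`tepop` detects transposable-element (TE) insertions that are absent from a
reference genome, from paired-end resequencing of single individuals, and
compares the resulting insertion landscapes between species with different
mating systems. The method is the classic discordant-pair approach:
individuals are mapped against a *combined reference* — the repeat-masked
genome plus a library of TE sequences labelled by family (LTR retro-
transposons, non-LTR retrotransposons, DNA transposons, Helitrons) — and a
pair with one mate uniquely on the genome and the other on a TE sequence is
evidence of an insertion near the genomic mate. Concordant genomic pairs
whose insert spans a candidate position count against it, giving a
per-sample insertion frequency that acts as an allele-dosage proxy.

The package deliberately separates four concerns: a synthetic-data
generator that defines a complete toy study with known truth; the
per-sample evidence pipeline (alignment → pair classification → insertion
observations); cross-sample genotyping and merging; and the population-
genetic summaries and tests. Real data enter through the same interfaces
(SAM from an external aligner, GFF3 gene annotation, BED pericentromeres);
the built-in exact matcher only serves the synthetic fixtures.

## Frequency estimation and why sides are averaged

For one candidate insertion in one sample, let $s$ be the number of
TE-supporting pairs and $d$ the number of spanning pairs whose inner
interval (the gap strictly between the two mates) contains the position
estimate. The frequency primitive is

$$ \hat f = \frac{s}{s + d}, $$

which is near 1 for homozygous and near 0.5 for heterozygous insertions.
One geometric subtlety matters: a full-length TE insertion is longer than
the sequencing insert, so a carrier haplotype presents *two* junctions
(left and right), each generating supporting pairs, while the non-carrier
haplotype presents a single spanning region. Pooling both sides into one
ratio would therefore concentrate heterozygotes near $2/3$ rather than
$1/2$: per side the expected support window spans $F - 2L$ positions
(fragment length $F$, read length $L$) per carrier haplotype, and the
spanning window also spans about $F - 2L$ positions per non-carrier
haplotype. For a both-sided detection the package consequently computes the
ratio per side and averages,

$$ \hat f = \tfrac12\left(\frac{s_{\mathrm{fwd}}}{s_{\mathrm{fwd}} + d} +
  \frac{s_{\mathrm{rev}}}{s_{\mathrm{rev}} + d}\right), $$

matching the behaviour of the established pooled-sample implementation of
this method and keeping heterozygotes centred on 0.5 (homozygotes are
unaffected: $d = 0$ gives 1 either way). Single-sided detections use the
plain ratio.

## Clustering and merging: transitive chaining

Within a sample, same-family same-side supporting positions are sorted and
chained greedily: a pair extends the open cluster when it lies within
`cluster_window` of the previous position. In one dimension this greedy
rule is exactly single-linkage transitive closure, which the test suite
verifies against a brute-force closure oracle. The default window,
`insert_mean + 3·insert_sd` (390 bp for the default 300 ± 30 geometry), is
the span within which a single junction can scatter its supporting mates.
A forward and a reverse cluster of one family whose innermost positions
fall within the window are joined into a both-sided observation positioned
at the floor of their midpoint; both-sidedness is retained as a
high-confidence flag. Single-sided clusters are kept if they reach
`min_support` (default 2 pairs) because per-sample coverage in studies of
this kind is modest; discarding them would cost sensitivity at
heterozygous sites.

Across samples, observations within `identity_window = 200` bp on the same
chromosome are the same insertion site. Two merge rules are implemented
because the choice is genuinely open: transitive chaining (default) and
anchor-based merging, where a site admits only observations within 200 bp
of its first member. Chaining is the default because it is symmetric and
order-invariant; the anchor rule is available for users worried about
chained sites drifting beyond 200 bp total span. Merging additionally
requires matching TE family (toggleable); this prevents chimeric sites
when two elements insert close together, at the cost of splitting a site
if the same insertion were detected under different families (impossible
for the synthetic fixtures, rare in practice). Observations in the error
band (frequency < 0.2) are dropped *before* merging, so an error call never
seeds a site, but a sample is still recorded absent at sites seeded by
other samples. The consensus coordinate is the floor of the mean member
position — nothing downstream depends on sub-window accuracy.

## Genotype thresholds

Calls follow the strict-inequality rule: frequency above 0.8 is
homozygous, below 0.2 is an error treated as absent, anything else —
including exactly 0.2 and 0.8 — is heterozygous. The hybrid experiment
(below) is the empirical justification: pure selfed samples pile up near
frequency 1 with a gap below ~0.8, and a merged hybrid fills the
intermediate band at sites carried by only one parent.

## Population frequencies, subsampling, spectra

Selfing species are treated as fully homozygous: any carrier counts as 2
copies and the population frequency of a site is carriers/individuals.
For the outcrosser each haplotype is an independent draw:
$(2\,\mathrm{hom} + \mathrm{het}) / 2n$. To keep species comparable,
frequencies are computed on a seeded random subsample of 8 individuals per
selfing species and half of that (4 individuals, 8 haplotypes) for the
outcrosser. Heterozygous calls that occur in selfers (possible with noisy
frequencies) are counted as carriers, consistent with the homozygosity
assumption.

Spectra bin frequencies over $(0, 1]$ with eight right-closed bins of
width 1/8 by default, matching the 8 samples/haplotypes, and carry 95%
percentile-bootstrap confidence intervals from `n_boot = 200` resamples.
The bootstrap unit is the *site*: resampling individuals would change the
frequencies themselves, and with many sites the resulting intervals are
narrow, consistent with how such intervals behave in practice. Sites at
frequency 1 (fixed in the sample) can be excluded with
`include_fixed = FALSE` to check that contrasts are not driven by fixed
insertions. Zero-frequency sites are rejected by contract — a site must
segregate in the subsample to enter the spectrum.

## Compartments and distance to genes

Pericentromeres are an input (BED); the synthetic generator places one
central pericentromere covering a configurable fraction of each
chromosome, with genes confined to the arms — emulating the gene-rich
arms / TE-dense pericentromere organisation of small plant genomes. A
site belongs to `centromeric` when its consensus position falls in a
pericentromere interval, so arms + centromeric counts partition the
genome-wide counts exactly (a tested invariant). Copy number is
presence-based by default (heterozygous and homozygous each count one
site), because "number of insertions" is the natural reading; allele-dosage
counting (hom = 2) is a flag.

Distance to the nearest gene uses half-open coordinate arithmetic from the
site's consensus position to the nearer gene edge: 0 inside a gene, and
symmetric on the two flanks so that a site midway between two genes is
equidistant from both. Distances are tabulated in 100-bp bins
$[k \cdot 100, (k+1) \cdot 100)$ as mean insertions per individual per bin
with the standard error across individuals of each species.

## Statistical tests

The four comparisons wrap the standard R implementations
(`kruskal.test`, `wilcox.test`, `glm(family = poisson)`): Kruskal–Wallis
H with tie correction across species; Wilcoxon signed-rank V for paired
comparisons (zero differences dropped; exact null for small samples,
normal approximation with continuity correction for large ones);
Mann–Whitney U with the first-group convention ($U$ = pairs where the
first group wins); and a log-link Poisson regression whose group
coefficients are log mean ratios with Wald z. The test suite verifies each
contract against an independent oracle — the rank formula for H, full
enumeration of sign assignments for V, pair counting for U, and the
closed-form categorical MLE for the GLM — and the acceptance suite checks
type-I calibration at $\alpha = 0.05$ over 2,000 null replicates per test.
No multiple-testing correction is applied anywhere, matching the analysis
style the package reproduces. The exact pairing units behind published
signed-rank statistics of this kind are typically not stated; the package
therefore declares its own unit (per-site cross-sample indicators,
configurable) and treats reproduction of any specific printed statistic as
out of scope.

## What the simulator emulates, and what it does not

`build_reference()` draws uniform-random chromosomes (no compositional
bias), places non-overlapping genes on the arms by multinomial gap
allocation, and generates a TE library of ≥ 400-bp random sequences, four
families, all mutually distinct. TE sequences are copied verbatim into
carriers — no within-copy divergence by default (a per-copy mutation rate
parameter exists but defaults to 0) — so the built-in exact matcher is a
valid aligner for the fixtures. `simulate_population()` draws a pool of
true sites (≥ 500 bp apart and from chromosome ends, pericentromere-
enriched), assigns each species a presence probability and a per-site
frequency from its profile, and genotypes individuals: selfers carry
homozygously with probability equal to the site frequency; outcrossers
draw two haplotypes under Hardy–Weinberg. `simulate_reads()` inserts the
TE sequences into the two haplotypes and draws inward-oriented pairs with
normal fragment lengths and Poisson pair counts,
$\mathbb{E}[\text{pairs}] = \text{coverage} \times G / (2L)$, with
constant base qualities.

The default three-species design mirrors the sampling structure of the
mating-system comparisons this package supports: an outcrosser (8
individuals, rare-skewed frequencies, Beta(0.6, 1.2), 90% of the pool
segregating), a recent selfer (24 individuals, Beta(1.3, 1.1), 95%
segregating) and an older selfer (10 individuals, high-frequency-skewed
Beta(4, 1), 45% segregating — fewer, older, more often fixed insertions).
The frequency architectures are free parameters of the simulator, chosen
once to produce those qualitative contrasts; they are not estimates of any
real species.

Consequently, passing tests demonstrate that the pipeline recovers what it
simulates — positions, genotypes, spectra, orderings — under idealised
conditions: no sequencing error (an `error_rate` parameter exists; the
exact matcher simply drops erroneous reads), no nested or truncated
insertions, no target-site duplications, no split-read evidence, no
reference-allele absence calling, and uniform mappability outside the
masked repeats. They do not certify performance on real libraries with
indels, adapter artefacts or diverged TE copies; for real data an external
aligner and its MAPQ model replace the built-in matcher (records with
MAPQ < 20 or secondary/supplementary flags are treated as non-unique).

## Validation experiments

Three self-checks run end to end on simulated reads. The *hybrid check*
merges the reads of two fully homozygous parents with partially disjoint
insertion sets: each parent alone should sit near frequency 1, and sites
carried by exactly one parent should drop toward 0.5 and be called
heterozygous in the hybrid — the qualitative signature that frequency-based
genotype calling works. The *pooled-versus-individual* check merges all
individuals of each species into one pooled sample and verifies the
species abundance ranking (and the Kruskal–Wallis conclusion) is the same
in both calling modes. The *reference swap* reruns detection against a
diverged copy of the genome (1% substitutions by default, built by
`diverge_reference()`) and/or a restricted TE library
(`subset_te_library()`), and verifies that the between-species ordering —
not the absolute counts, which shrink — is preserved. With exact matching,
1% divergence removes about $1 - 0.99^{108} \approx 66\%$ of read
placements, so retained counts drop to roughly a third while the ordering
stands; this is the synthetic analogue of mapping all species against an
outgroup assembly.

## Numerical and reproducibility choices

All randomness flows from one root seed through named substreams
(`substream_seed(seed, label)`, a modular polynomial hash kept below
$2^{31}$), so stages can be rerun independently and a pipeline run is
byte-reproducible — TSV outputs carry a header with the config hash and
seed, and the acceptance suite checks md5 equality of complete reruns.
Ties and boundaries are fixed deterministically: cluster joining picks the
closest forward/reverse pair first (then leftmost); a sample with several
member observations at one site contributes its best-supported one
(support, then frequency, then position); consensus positions round down;
spectrum bins are right-closed. Degenerate inputs are flagged rather than
guessed at: empty evidence yields an empty observation table, an empty
spectrum is marked `degenerate`, all-zero signed-rank differences and
all-zero Poisson groups are flagged.

## Problem sizes used by the tests

The acceptance suite exercises the full pipeline on a 500-kb genome with
50 true sites and three species of 8 individuals at 20× coverage — small
enough to run in minutes, large enough that recovery, genotype accuracy
and the species contrasts are measured on hundreds of calls. Calibration
checks use 1,000 random merge instances, 200 bootstrap-coverage
replicates, 2,000 null replicates per statistical test, and 300
power-ordering replicates. `scripts/acceptance.R` recomputes all headline
quantities from scratch with any seed.

## Known limitations

Detection sensitivity is bounded by coverage and the $F - 2L$ support
window; at 20× a heterozygous site yields only ~4 supporting pairs per
side, so the 0.2/0.8 thresholds misclassify a few percent of
heterozygotes. Position estimates are innermost-midpoints, typically
within a few bp but biased outward for single-sided detections. The
frequency denominator ignores spanning pairs lost to the insertion allele
(reads overlapping the junction map nowhere), which slightly inflates
frequencies at low coverage. Merging by 200-bp chaining can, in
pathological dense clusters, link observations whose extremes are farther
than 200 bp apart (the anchor mode avoids this). None of these affect the
simulated-study conclusions, but they are the right places to look first
when real data misbehave.
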