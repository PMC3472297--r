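---
title: "The cnasynth signal model: synthetic tumour SNP-array data for caller benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cnasynth signal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasynth)
```

## Why synthesize tumour genotyping data

Calling somatic copy-number alterations (CNAs) and loss of heterozygosity
(LOH) from SNP-array log R ratio (LRR) and B allele frequency (BAF) signals
is hard in tumours for three reasons: the genome-wide DNA index shifts the
LRR baseline, normal-cell contamination shrinks both signals towards their
diploid values, and subclonal heterogeneity superimposes mixtures of cell
populations with different genotypes.  Benchmarking callers therefore needs
data where the complete truth — every breakpoint, copy number, LOH state
and subclone — is known.  `cnasynth` generates such data from an explicit
generative model and scores caller output against the emitted truth.

## The model

A sample is a mixture of $J$ cell types: one normal diploid population with
genome-wide proportion $w_1$ (the contamination) and $J-1$ tumour clones.
At SNP $i$ the LRR is

$$\mathrm{lrr}_i = \sum_{j=1}^{J} w_{i,j}\, r_{x_{i,j}} + l + c_i,$$

where $x_{i,j}$ is the copy number of cell type $j$ at SNP $i$, each level
$r_x \sim N(\mu_x, \sigma_x)$ is drawn independently per SNP and per clone,
$l$ is the sample-wide baseline shift, and $c_i$ is an autocorrelated bias
following an ARMA (Box–Jenkins) process.  Proportions are positive and sum
to one at every locus, and $w_1$ is constant genome-wide.

The BAF is the weighted allelic ratio plus noise,

$$\mathrm{baf}_i = \frac{\sum_j w_{i,j}\, z_{i,j}}{\sum_j w_{i,j}\, x_{i,j}} + n_i,$$

with $z_{i,j}$ the number of B alleles among the $x_{i,j}$ copies.  The
noise $n_i$ is genotype-dependent: heterozygous loci receive a full
Gaussian of sd $\sigma_{he}$; homozygous loci (noiseless BAF exactly 0
or 1) are a mixture of a point mass at the extreme, taken with probability
$\pi$, and a half-Gaussian of sd $\sigma_{ho}$ pointing into the unit
interval.  Emitted BAF is clipped to $[0,1]$, since instrument BAF is
bounded by construction.

The discrete layer is constrained by the germline.  Normal genotypes are
binomial in the population B allele frequency (PFB) $p_i$:
$z_{i,1} \sim B(2, p_i)$.  Tumour clones are necessarily homozygous for the
same allele wherever the normal genome is homozygous; where it is
heterozygous, $0 \le z_{i,j} \le x_{i,j}$.  Finally, SNPs in one region are
coherent: a region represents a single event per clone, so across the
region's heterozygous SNPs the clone genotypes are either identical or the
joint mirror image (A and B swapped) of one another, depending on which
parental haplotype carries the B allele at each SNP.

### The phase mechanism

The model realizes coherence through an explicit haplotype event: per clone
a region keeps `h1_copies` copies of parental haplotype 1 and
`cn - h1_copies` of haplotype 2.  Each heterozygous SNP's B allele sits on
haplotype 1 with probability 0.5, i.i.d., sampled once and shared across
clones.  This is the simplest mechanism that generates the mirrored BAF
band pattern of real allelic imbalance, and it makes the mirror ambiguity
of the coherence restriction appear naturally.  Linkage disequilibrium and
realistic haplotype structure are deliberately not modelled.

Germline LOH is represented as a run of homozygosity: the normal genotype
itself is resampled as $2\cdot\mathrm{Bernoulli}(p_i)$, which the tumour
clones then propagate.  Somatic LOH is a region where one and the same
parental haplotype has zero copies in every tumour clone while the normal
genome is diploid-heterozygous (this includes copy-neutral LOH at CN2).

## Parameters, defaults and their rationale

| Parameter | Default | Meaning |
|---|---|---|
| $\mu_x$ | $-2.0, -0.55, 0, 0.30, 0.54, 0.70$ for CN 0–5 | expected LRR per copy number (LRR units); diploid anchored at 0 |
| $\sigma_x$ | 0.2 | per-clone LRR noise sd, all copy numbers |
| $\sigma_{he}$ | 0.03 | heterozygous BAF noise sd |
| $\sigma_{ho}$ | 0.015 | homozygous half-Gaussian sd (half of $\sigma_{he}$, as observed on arrays) |
| $\pi$ | 0.30 | proportion of homozygous probes forced to exactly 0/1 |
| ARMA | AR(1), $\rho = 0.995$, marginal sd 0.05 | slow genomic-wave-like autocorrelated bias |
| shift law | slope 0.6, sd 0.05 | $l \sim N(-0.6\,(DI_{\mathrm{eff}}-1),\ 0.05)$ |
| contamination | 0, 0.25, 0.50, 0.75 | the benchmark sweep values (any value in $[0,1)$ accepted) |

Three of these deserve comment.  First, published descriptions of this
class of model quote homozygous/heterozygous BAF sds an order of magnitude
larger (0.15/0.3) than what high-quality arrays show (0.02–0.03); with sd
0.3 the characteristic tight BAF bands could not exist, so we treat the
large values as a decimal slip and default to 0.03/0.015, keeping any value
configurable.  Second, the $\mu_x$ table is not uniquely recoverable from
the literature ("half of" another method's values); the default
approximates observed Illumina levels and every entry can be overridden.
Third, the BAF noise equation in the source description assigns the
half-Gaussian sds inconsistently with its own prose; we follow the prose
(both homozygous extremes use $\sigma_{ho}$, heterozygous uses
$\sigma_{he}$, point-mass weight $= \pi$), which is self-consistent.

The baseline shift is drawn from the DNA-index relationship with the
*effective* index $DI_{\mathrm{eff}} = (1-w_1)\,DI + w_1$, because the
hybridized mixture includes the contaminating diploid cells.  The slope and
sd of the law are package defaults (the empirically fitted coefficients on
real breast-cancer samples are not printed anywhere recoverable) and are
configurable.  The empirical real-data relationships (contraction
$\approx 0.49\cdot$purity, DNA-index/shift $R^2 = 0.89$) are properties of
external sample sets; the linear-mixing model here yields contraction
exactly equal to purity, which is what the package asserts.

## Pattern presets

Five presets emulate characteristic tumour profiles.  Each is a fixed menu
of region archetypes with exact SNP budgets over a 12,000-SNP genome:

| preset | DNA index | labelled composition |
|---|---|---|
| `near_diploid` | 1.03 | 45.4% diploid-heterozygous |
| `near_triploid` | 1.32 | 40.3% CN3 |
| `near_tetraploid` | 1.57 | 38.3% CN4 |
| `loh_enriched` | 1.31 | 40.1% LOH (germline or somatic) |
| `complex` | 1.39 | 47.6% multi-subclone |

Composition is SNP-length-weighted (consistent with the DNA index being a
length-weighted mean), and the DNA index is computed tumour-only —
contamination is a separately swept factor.  Because budgets are fixed,
every replicate hits the targets exactly; replicate-to-replicate
variability lies in the number of fragments (kept within 205–280), the
fragment lengths (drawn from \{10, 20, 40, 80, 160\} SNPs by a
dynamic-programming partition that always sums exactly to the budget) and
the shuffled placement across chromosomes of ~2,000 SNPs.  The complex
preset includes a three-subclone archetype (homozygous deletion 25%,
allele duplication 50%, allele triplication 25%) alongside two-subclone
mixtures.

The exact archetype menus are a design choice: the original preset
definitions are not recoverable, so the menus were solved once from the
published summary targets (the linear system of budgets vs DNA index and
composition) and then frozen.  They were not adjusted afterwards.

Scaffold mode replaces the preset menu with a user-supplied ordered region
list (length, per-clone copy number, allelic ratio, germline-LOH flag,
optional subclone fractions), preserving the spatial distribution of real
rearrangements — hybrid data between synthetic and real.  Two genome-wide
options apply there: a second, longer-memory ARMA component (long-distance
waves) and an overall intra-tumour complexity scalar that converts
single-clone regions into two-subclone variants with the given probability
(the conversion adds a diploid subclone at fraction 0.3; the exact
mechanism is unspecified in the literature, so this simple convention is
documented rather than claimed).

## Evaluation harness

Recall follows the region-overlap rule: a truth region is recalled when a
*single* call with the same copy number overlaps at least half of the
region's length (basepairs, half-open intervals; a tie at exactly 50%
counts; the fraction is configurable because results change little with
it).  Partial calls are never pooled.  With LOH-aware matching, LOH
presence/absence must also agree, but germline vs somatic is not
distinguished.  Diploid-heterozygous regions are excluded from both truth
and calls before any counting.

Because calls often span several true regions in densely altered genomes, a
region-level false discovery rate is ill-defined; the harness instead
reports the fraction of calls whose copy number differs from that of the
truth region with maximal overlap (ties broken by the leftmost region; a
call overlapping nothing counts as wrong).  This approximation favours
methods with coarse breakpoints, so values are not comparable across
callers — it is reported for its diagnostic value about how wrong calls
distribute over copy numbers.

## What a green test establishes — and what it does not

The synthetic data contains none of the platform biases of real arrays: no
GC-content waves correlated with sequence context (the ARMA component is
autocorrelated but content-agnostic), no dye bias or BAF asymmetry, no
probe-specific outliers, no linkage disequilibrium.  A caller that performs
well here handles the *model's* difficulties (shift, contamination,
subclones, noise); robustness to platform artefacts must be established on
real or hybrid data.  Conversely, the generated truth is exact, so recall
and FDR numbers have no annotation uncertainty.

## Numerical choices and degenerate inputs

* Zero-noise settings are handled exactly: `sigma = 0` Gaussians return
  their means bit-for-bit, an ARMA innovation sd of 0 returns exact zeros,
  and `pi_extreme = 1` forces exact extremes, so synthesized signals equal
  the closed-form expectations identically — this is tested, not just
  asserted.
* SNPs whose weighted total copy number is zero have no defined BAF; they
  are emitted as `NA` in memory and `NaN` on disk, with a warning.
* ARMA stationarity is validated via the AR characteristic roots; burn-in
  is at least 10x the order and extended for near-unit-root processes.
* Intervals are 0-based half-open in basepairs on disk (BED convention);
  the signal table uses 1-based positions (array convention).  A SNP at
  1-based position $p$ belongs to $[s, e)$ iff $p - 1 \in [s, e)$.
* Per-replicate seeds are derived deterministically from the base seed, so
  replicate sets are reproducible as a whole and individually.

## Known limitations

* Phases are independent across SNPs; runs of homozygosity arise only where
  configured, not from population structure.
* The packaged PFB distribution is a synthetic stand-in (beta mixture with
  point masses at 0 and 1), not real array frequencies; load a real `.pfb`
  for exact replication.
* Preset targets are met exactly by construction, so preset variability
  understates biological variability between tumours of the same class.
* The FDR approximation inherits the caveats above; no attempt is made to
  reproduce published comparisons of specific callers.
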