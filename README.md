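# cnasynth

Synthetic tumour SNP-array genotyping data — and a benchmarking harness —
for copy-number alteration (CNA) and loss-of-heterozygosity (LOH) callers.

Detecting CNAs in cancer from SNP-array signals is complicated by three
tumour-specific factors: a shifted log R ratio (LRR) baseline when the DNA
index (half the mean copy number) departs from 1, normal-cell contamination
that shrinks both LRR and B allele frequency (BAF) towards their diploid
values, and intra-tumour subclones that superimpose cell populations with
different genotypes.  `cnasynth` implements a generative model that
integrates all three, producing per-SNP LRR/BAF tables with exact truth
annotations on which callers can be stress-tested.

## The model in brief

For SNP *i* and cell types *j* = 1..*J* (normal cells plus tumour clones,
proportions *w*, constant contamination *w*₁):

```
lrr_i = Σ_j w_ij · r_{x_ij} + l + c_i        r_x ~ N(μ_x, σ_x)
baf_i = Σ_j w_ij z_ij / Σ_j w_ij x_ij + n_i
```

where *x* is copy number, *z* the B-allele count, *l* the sample-wide
baseline shift (drawn from its DNA-index relationship), *c* an ARMA
autocorrelated bias (genomic waves) and *n* a genotype-dependent noise:
full Gaussian for heterozygous SNPs, a point-mass/half-Gaussian mixture for
homozygous ones (30% of homozygous probes sit exactly at 0 or 1 by
default).  Germline genotypes are Binomial(2, PFB); tumour genotypes obey
the germline (homozygous loci stay homozygous) and a per-region coherence
restriction realized through parental-haplotype phase.  Evaluation uses the
region-overlap recall rule (a region is recalled when a single call with
the same copy number covers ≥ 50% of its length) and a wrong-copy-number
FDR approximation.  The methods vignette
(`vignettes/signal-model.Rmd`) derives and motivates all of it.

## Worked example

```r
library(cnasynth)

s <- build_pattern("near_triploid", contamination = 0.25, seed = 42)
s
#> <cna_sample> 12000 SNPs on 6 chromosomes, 263 truth regions
#>   preset: near_triploid | contamination: 0.25 | DNA index: 1.320 | shift: -0.074

round(100 * truth_composition(s), 1)
#>     cn0     cn1     cn2     cn3     cn4     cn5 cn2_het     loh complex
#>     0.0     6.7    39.5    40.3    10.2     3.3    31.2    21.7     0.0
```

40.3% of the genome is in copy-number-3 state and the DNA index is 1.32 —
the defining targets of the near-triploid pattern; the drawn baseline shift
(−0.074) follows from the contamination-adjusted DNA index.  Write the
sample for a caller, then score the caller's output:

```r
write_signal_table(s, path = "sample.signals.tsv")  # Name/Chr/Position/LRR/BAF
write_truth_bed(s$truth, "sample.truth.bed")

calls <- read_calls("caller_output.tsv")            # chrom start end cn [loh]
recall_table(list(s$truth), list(calls), contamination = 0.25,
             by = c("contamination", "copy_number"))
```

Scoring the truth against itself (with LOH annotations kept) shows the
harness conventions — diploid-heterozygous regions are excluded, everything
else is recalled:

```r
#>   contamination copy_number n_truth n_recalled recall
#> 1          0.25           1      17         17      1
#> 2          0.25           2      22         22      1
#> 3          0.25           3     106        106      1
#> 4          0.25           4      27         27      1
#> 5          0.25           5       9          9      1
```

The linear-mixing model makes LRR contraction equal tumour purity; a
zero-noise contamination sweep recovers it exactly:

```r
cfg <- sample_config(lrr_model = lrr_model(sigma = 0), arma = arma_model(),
                     baf_noise = baf_noise_model(0, 0, 1),
                     shift_law = c(slope = 0.6, sd = 0))
sweep <- lapply(c(0, 0.25, 0.5, 0.75), function(w)
  build_pattern("near_triploid", w, seed = 42, config = cfg))
estimate_contraction(sweep)
#> <contraction_fit> q ~ purity: slope 1.0000, intercept -0.0000, R^2 1.0000
```

## Command line

```sh
Rscript inst/scripts/generate.R --pattern complex --contamination 0.5 \
    --replicates 10 --seed 1 --config config.yaml --out out/
Rscript inst/scripts/generate.R --scaffold scaffold.tsv --contamination 0.25 --out out/
Rscript inst/scripts/evaluate.R --truth out/sample_001.truth.bed \
    --calls calls.tsv --group-by copy_number,length --out report.tsv
```

Scaffold mode lays regions down in a user-supplied order (e.g. derived from
segmentation of a real tumour), producing hybrid synthetic/real samples;
see `?read_scaffold` for the TSV format and `?config_from_list` for the
YAML keys.

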