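Package: cnasynth
Title: Synthetic Tumour SNP-Array Signals for Copy-Number Caller Benchmarking
Version: 0.1.0
Author: cnasynth developers
Maintainer: cnasynth developers <cnasynth-dev@example.org>
Description: Generative model for per-SNP log R ratio (LRR) and B allele
    frequency (BAF) signals of tumour samples genotyped on SNP arrays, under
    somatic copy-number alterations, germline and somatic loss of
    heterozygosity, normal-cell contamination and intra-tumour subclonal
    heterogeneity.  Provides pattern presets and scaffold-driven assembly of
    fully truth-annotated synthetic samples, PennCNV-style signal and PFB
    file I/O, and an evaluation harness computing overlap-based recall and a
    wrong-copy-number false discovery rate for CNA/LOH callers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
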