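#' SNP probe scaffold
#'
#' A `snp_grid` is the probe-level backbone of a synthetic sample: one row per
#' SNP with its name, chromosome, basepair position and population B allele
#' frequency (PFB, the per-SNP population frequency of the B allele that
#' governs expected germline genotype proportions).
#'
#' @param probe_name character vector of unique probe identifiers.
#' @param chrom chromosome label per SNP; SNPs of a chromosome must be
#'   contiguous and their positions strictly increasing.
#' @param position integer basepair position (1-based).
#' @param pfb numeric in `[0, 1]`, population B allele frequency per SNP.
#' @return A `data.frame` of class `snp_grid`.
#' @seealso [make_snp_grid()] for the evenly spaced synthetic layout.
#' @export
snp_grid <- function(probe_name, chrom, position, pfb) {
  n <- length(probe_name)
  if (length(chrom) != n || length(position) != n || length(pfb) != n)
    stop_("snp_grid: all columns must have the same length")
  if (anyDuplicated(probe_name))
    stop_("snp_grid: probe names must be unique")
  if (any(!is.finite(pfb)) || any(pfb < 0 | pfb > 1))
    stop_("snp_grid: pfb values must lie in [0, 1]")
  chrom <- as.character(chrom)
  if (any(rle(chrom)$values != unique(chrom)))
    stop_("snp_grid: SNPs of a chromosome must be contiguous")
  for (ch in unique(chrom)) {
    p <- position[chrom == ch]
    if (any(diff(p) <= 0))
      stop_("snp_grid: positions must be strictly increasing within %s", ch)
  }
  out <- data.frame(probe_name = as.character(probe_name), chrom = chrom,
                    position = as.integer(position), pfb = as.numeric(pfb),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_grid", "data.frame")
  out
}

#' Build an evenly spaced synthetic SNP grid
#'
#' Probes are laid out on synthetic chromosomes at a fixed spacing; SNP `k`
#' (1-based within its chromosome) sits at `k * spacing_bp`, so the probe for
#' 0-based SNP index `i` falls inside the half-open basepair interval
#' `[i * spacing_bp, (i + 1) * spacing_bp)`.
#'
#' @param n_snps total number of SNPs.
#' @param pfb scalar or length-`n_snps` vector of PFB values.
#' @param snps_per_chrom chromosome size in SNPs (the last chromosome may be
#'   shorter); ignored when `chrom_sizes` is given.
#' @param spacing_bp distance between adjacent probes in basepairs.
#' @param chrom_sizes optional explicit vector of chromosome sizes in SNPs
#'   (must sum to `n_snps`).
#' @return A [snp_grid()].
#' @export
make_snp_grid <- function(n_snps, pfb = 0.5, snps_per_chrom = 2000L,
                          spacing_bp = 5000L, chrom_sizes = NULL) {
  if (!is_count(n_snps) || n_snps < 1) stop_("make_snp_grid: n_snps must be a positive integer")
  if (is.null(chrom_sizes)) {
    k <- n_snps %/% snps_per_chrom
    chrom_sizes <- c(rep(snps_per_chrom, k), n_snps - k * snps_per_chrom)
    chrom_sizes <- chrom_sizes[chrom_sizes > 0]
  }
  if (sum(chrom_sizes) != n_snps)
    stop_("make_snp_grid: chrom_sizes must sum to n_snps")
  if (length(pfb) == 1L) pfb <- rep(pfb, n_snps)
  chrom <- rep(sprintf("chr%d", seq_along(chrom_sizes)), chrom_sizes)
  within <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)
  snp_grid(probe_name = sprintf("snp%07d", seq_len(n_snps)),
           chrom = chrom,
           position = as.integer(within) * as.integer(spacing_bp),
           pfb = pfb)
}
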