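#' Cell population of a sample
#'
#' A sample is a mixture of one normal (diploid) cell type and one or more
#' tumour clones.  The normal fraction `w1` is constant genome-wide (normal
#' contamination does not change from probe to probe); within a region the
#' tumour clones split the remaining `1 - w1` according to region-level
#' subclone fractions.
#'
#' @param normal_fraction real in `[0, 1)`, proportion of normal cells.
#' @param subclone_fractions tumour-internal proportions, summing to 1.
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(normal_fraction = 0, subclone_fractions = 1) {
  if (!is.numeric(normal_fraction) || length(normal_fraction) != 1L ||
      normal_fraction < 0 || normal_fraction >= 1)
    stop_("cell_population: normal_fraction must lie in [0, 1)")
  if (any(subclone_fractions <= 0) ||
      abs(sum(subclone_fractions) - 1) > 1e-8)
    stop_("cell_population: subclone fractions must be positive and sum to 1")
  structure(list(normal_fraction = normal_fraction,
                 subclone_fractions = as.numeric(subclone_fractions),
                 n_cell_types = length(subclone_fractions) + 1L),
            class = "cell_population")
}

#' Region specification
#'
#' A contiguous run of SNPs sharing one copy-number event per tumour clone.
#' The allelic-imbalance descriptor `h1_copies` gives, per clone, the number
#' of copies of parental haplotype 1 retained by the event (so the clone
#' carries `cn - h1_copies` copies of haplotype 2).  A heterozygous-in-normal
#' SNP whose B allele is phased onto haplotype 1 then has B-allele count
#' `h1_copies` in that clone, and `cn - h1_copies` otherwise.
#'
#' LOH status is derived: `germline` when `germline_loh` is set (a run of
#' homozygosity in the normal genome), `somatic` when one and the same
#' parental haplotype has zero copies in every tumour clone while the normal
#' genome is diploid-heterozygous, `none` otherwise.
#'
#' @param n_snps region length in SNPs (alternative to `snp_end`).
#' @param snp_start,snp_end SNP-index interval, 0-based half-open.
#' @param cn integer copy number per tumour clone.
#' @param h1_copies copies of parental haplotype 1 per clone; defaults to the
#'   balanced split `ceiling(cn / 2)`.
#' @param fractions subclone fractions (sum 1); default equal split.
#' @param germline_loh force the normal genome homozygous across the region.
#' @param label optional region name used in error messages and truth files.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(n_snps = NULL, snp_start = 0L, snp_end = NULL,
                        cn = 2L, h1_copies = NULL, fractions = NULL,
                        germline_loh = FALSE, label = NULL) {
  if (is.null(snp_end)) {
    if (is.null(n_snps)) stop_("region_spec: give n_snps or snp_end")
    snp_end <- snp_start + n_snps
  }
  cn <- as.integer(cn)
  if (is.null(h1_copies)) h1_copies <- as.integer(ceiling(cn / 2))
  h1_copies <- as.integer(h1_copies)
  if (is.null(fractions)) fractions <- rep(1 / length(cn), length(cn))
  structure(list(snp_start = as.integer(snp_start),
                 snp_end = as.integer(snp_end),
                 cn = cn, h1_copies = h1_copies,
                 fractions = as.numeric(fractions),
                 germline_loh = isTRUE(germline_loh),
                 label = label %||% sprintf("region_%d_%d", snp_start, snp_end)),
            class = "region_spec")
}

#' Derived LOH status of a region
#'
#' @param region a [region_spec()].
#' @return `"germline"`, `"somatic"` or `"none"`.
#' @export
region_loh_status <- function(region) {
  if (region$germline_loh) return("germline")
  h2 <- region$cn - region$h1_copies
  if (all(region$h1_copies == 0L) || all(h2 == 0L)) return("somatic")
  "none"
}

#' Validate a region specification
#'
#' Diagnostics, not exceptions: returns a character vector naming every
#' violated rule (empty when the region is coherent).
#'
#' @param region a [region_spec()].
#' @param population optional [cell_population()] checked for consistency
#'   with the region (clone count, fraction sum).
#' @param max_copy_number configured copy-number ceiling.
#' @return character vector of violations.
#' @export
validate_region <- function(region, population = NULL, max_copy_number = 5L) {
  v <- character()
  if (region$snp_end <= region$snp_start)
    v <- c(v, sprintf("%s: empty region (snp_end <= snp_start)", region$label))
  if (any(region$cn < 0L | region$cn > max_copy_number))
    v <- c(v, sprintf("%s: copy number outside [0, %d]", region$label, max_copy_number))
  if (length(region$h1_copies) != length(region$cn))
    v <- c(v, sprintf("%s: h1_copies length differs from cn length", region$label))
  else if (any(region$h1_copies < 0L | region$h1_copies > region$cn))
    v <- c(v, sprintf("%s: imbalance descriptor incompatible with clone copy number",
                      region$label))
  if (length(region$fractions) != length(region$cn))
    v <- c(v, sprintf("%s: fractions length differs from cn length", region$label))
  if (any(region$fractions <= 0) || abs(sum(region$fractions) - 1) > 1e-8)
    v <- c(v, sprintf("%s: fractions sum != 1", region$label))
  if (!is.null(population)) {
    if (population$normal_fraction < 0 || population$normal_fraction >= 1)
      v <- c(v, "population: normal_fraction outside [0, 1)")
  }
  v
}

#' Draw germline genotypes for every SNP
#'
#' The normal-cell B-allele count at SNP `i` is binomial:
#' `z_i ~ Binomial(2, p_i)` with `p_i` the SNP's PFB.
#'
#' @param grid a [snp_grid()].
#' @param seed optional integer seed.
#' @return integer vector of B-allele counts in `{0, 1, 2}`.
#' @export
sample_normal_genotypes <- function(grid, seed = NULL) {
  stopifnot(inherits(grid, "snp_grid"))
  if (any(grid$pfb < 0 | grid$pfb > 1))
    stop_("sample_normal_genotypes: pfb outside [0, 1]")
  with_seed(seed, stats::rbinom(nrow(grid), 2L, grid$pfb))
}

#' Admissible tumour B-allele counts given the germline genotype
#'
#' Tumour cells are necessarily homozygous wherever the normal genome is
#' homozygous (the lost/duplicated material can only carry the allele that is
#' there); where the normal genome is heterozygous the B-allele count is only
#' bounded by the clone's copy number.
#'
#' @param z_normal germline B-allele count, in `{0, 1, 2}`.
#' @param x_tumour clone copy number, `>= 0`.
#' @return integer vector of admissible `z` values.
#' @export
enumerate_tumour_genotypes <- function(z_normal, x_tumour) {
  if (!is_count(z_normal) || !(z_normal %in% 0:2))
    stop_("enumerate_tumour_genotypes: z_normal must be 0, 1 or 2")
  if (!is_count(x_tumour) || x_tumour < 0)
    stop_("enumerate_tumour_genotypes: x_tumour must be a non-negative integer")
  x_tumour <- as.integer(x_tumour)
  if (z_normal == 0L) return(0L)
  if (z_normal == 2L) return(x_tumour)
  0:x_tumour
}

#' Assign per-SNP, per-clone genotypes across a region
#'
#' One copy-number event per clone (the `h1_copies` imbalance descriptor) is
#' shared by the whole region; each heterozygous-in-normal SNP receives its
#' B-allele count through a randomly sampled phase (which parental haplotype
#' carries the B allele, `P = 0.5` i.i.d., shared across clones), producing
#' the mirrored BAF bands characteristic of allelic imbalance.  SNPs
#' homozygous in the normal genome force the tumour clones homozygous for
#' the same allele.  In germline-LOH regions the normal genotype itself is
#' resampled as a run of homozygosity (`z = 2 * Bernoulli(p_i)`).
#'
#' @param region a [region_spec()].
#' @param normal_z germline B-allele counts for the region's SNPs.
#' @param pfb per-SNP PFB for the region (needed for germline-LOH regions).
#' @param seed optional integer seed.
#' @return An object of class `genotype_matrix`: integer matrices `x` and `z`
#'   (SNPs x cell types, column 1 the normal clone) plus the sampled `phase`
#'   (`TRUE` = B allele on parental haplotype 1).
#' @export
assign_region_genotypes <- function(region, normal_z, pfb = NULL, seed = NULL) {
  stopifnot(inherits(region, "region_spec"))
  n <- region$snp_end - region$snp_start
  if (length(normal_z) != n)
    stop_("assign_region_genotypes: normal_z must cover the region (%d SNPs)", n)
  if (any(region$h1_copies < 0L) || any(region$h1_copies > region$cn))
    stop_("%s: imbalance descriptor incompatible with clone copy number", region$label)
  with_seed(seed, {
    z1 <- as.integer(normal_z)
    if (region$germline_loh) {
      if (is.null(pfb))
        stop_("%s: germline-LOH region needs pfb values", region$label)
      z1 <- 2L * (stats::runif(n) < pfb)
    }
    phase <- stats::runif(n) < 0.5
    k <- length(region$cn)
    x <- cbind(2L, matrix(rep(region$cn, each = n), nrow = n))
    z <- matrix(0L, nrow = n, ncol = k + 1L)
    z[, 1L] <- z1
    for (j in seq_len(k)) {
      cnj <- region$cn[j]
      h1 <- region$h1_copies[j]
      zj <- integer(n)
      het <- z1 == 1L
      zj[het] <- ifelse(phase[het], h1, cnj - h1)
      zj[z1 == 2L] <- cnj
      z[, j + 1L] <- zj
    }
    structure(list(x = x, z = z, phase = phase, label = region$label),
              class = "genotype_matrix")
  })
}

#' Check the invariants of a genotype matrix
#'
#' Verifies `0 <= z <= x` everywhere, homozygosity propagation from the
#' normal clone, and the within-region coherence restriction (for any two
#' heterozygous-in-normal SNPs, the clone genotypes of one are either equal
#' to or the joint mirror image of the other's).
#'
#' @param gm a `genotype_matrix`.
#' @return character vector of violations (empty if all invariants hold).
#' @export
validate_genotypes <- function(gm) {
  v <- character()
  if (any(gm$z < 0L) || any(gm$z > gm$x))
    v <- c(v, "z outside [0, x]")
  z1 <- gm$z[, 1L]
  k <- ncol(gm$z) - 1L
  for (j in seq_len(k)) {
    zj <- gm$z[, j + 1L]
    xj <- gm$x[, j + 1L]
    if (any(zj[z1 == 0L] != 0L) || any(zj[z1 == 2L] != xj[z1 == 2L]))
      v <- c(v, sprintf("clone %d not homozygous where normal is homozygous", j))
  }
  het <- which(z1 == 1L)
  if (length(het) > 1L) {
    s <- het[1L]
    same <- mirror <- rep(TRUE, length(het))
    for (j in seq_len(k) + 1L) {
      same <- same & gm$z[het, j] == gm$z[s, j]
      mirror <- mirror & gm$z[het, j] == gm$x[het, j] - gm$z[s, j]
    }
    if (!all(same | mirror))
      v <- c(v, "coherence restriction violated among heterozygous SNPs")
  }
  v
}
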