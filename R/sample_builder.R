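#' Sample-level configuration
#'
#' Bundles every tunable of the generative model: the contamination level
#' `w1` (fraction of normal cells), the LRR level model, the autocorrelated
#' bias, the BAF noise mixture, the law linking DNA index to the LRR
#' baseline shift, the PFB source and the genome layout.
#'
#' @param contamination normal-cell fraction `w1` in `[0, 1)`; the
#'   benchmark sweep uses 0, 0.25, 0.50 and 0.75.
#' @param lrr_model an [lrr_model()].
#' @param arma an [arma_model()] for the probe-to-probe autocorrelated bias;
#'   the default AR(1) with coefficient 0.995 and marginal sd 0.05 mimics
#'   slow genomic waves.
#' @param baf_noise a [baf_noise_model()].
#' @param shift_law named vector `c(slope, sd)`: the baseline shift is drawn
#'   `l ~ N(-slope * (DI_eff - 1), sd)` where `DI_eff` is the
#'   contamination-adjusted DNA index.
#' @param pfb a [pfb_source()].
#' @param snps_per_chrom approximate chromosome size in SNPs (chromosome
#'   breaks are placed at the first region boundary past this size).
#' @param spacing_bp probe spacing in basepairs.
#' @param waves optional second [arma_model()] with longer memory for
#'   genome-wide long-distance waves (scaffold mode); off by default.
#' @param complexity scalar in `[0, 1]`: probability that a scaffold region
#'   with a single non-diploid clone is converted into a 2-subclone variant
#'   (an extra diploid subclone at fraction 0.3); 0 disables.
#' @param max_copy_number copy-number ceiling for validation.
#' @return An object of class `sample_config`.
#' @export
sample_config <- function(contamination = 0,
                          lrr_model = cnasynth::lrr_model(),
                          arma = arma_model(ar = 0.995,
                                            innovation_sd = 0.05 * sqrt(1 - 0.995^2)),
                          baf_noise = baf_noise_model(),
                          shift_law = c(slope = 0.6, sd = 0.05),
                          pfb = pfb_source("packaged_empirical"),
                          snps_per_chrom = 2000L,
                          spacing_bp = 5000L,
                          waves = NULL,
                          complexity = 0,
                          max_copy_number = 5L) {
  if (contamination < 0 || contamination >= 1)
    stop_("sample_config: contamination must lie in [0, 1)")
  stopifnot(inherits(lrr_model, "lrr_model"), inherits(arma, "arma_model"),
            inherits(baf_noise, "baf_noise_model"), inherits(pfb, "pfb_source"))
  if (is.null(names(shift_law))) names(shift_law) <- c("slope", "sd")
  structure(list(contamination = contamination, lrr_model = lrr_model,
                 arma = arma, baf_noise = baf_noise, shift_law = shift_law,
                 pfb = pfb, snps_per_chrom = as.integer(snps_per_chrom),
                 spacing_bp = as.integer(spacing_bp), waves = waves,
                 complexity = complexity,
                 max_copy_number = as.integer(max_copy_number)),
            class = "sample_config")
}

format_subclones <- function(cn, h1, frac) {
  paste(sprintf("%d:%d:%g", cn, h1, frac), collapse = "|")
}

parse_subclones <- function(s) {
  lapply(strsplit(s, "|", fixed = TRUE), function(parts) {
    m <- do.call(rbind, strsplit(parts, ":", fixed = TRUE))
    data.frame(cn = as.integer(m[, 1L]), h1 = as.integer(m[, 2L]),
               frac = as.numeric(m[, 3L]))
  })
}

as_truth <- function(x) {
  if (inherits(x, "cna_sample")) x <- x$truth
  stopifnot(is.data.frame(x), all(c("n_snps", "subclones", "loh") %in% names(x)))
  x
}

# Core assembly shared by preset and scaffold modes: takes an ordered list
# of region_spec-like records (cn/h1/frac/germ/n_snps/label) and produces a
# full cna_sample.  Runs inside the caller's seeded RNG stream.
assemble_sample <- function(records, contamination, config, preset_name = NA_character_) {
  n_snps_vec <- vapply(records, `[[`, 0L, "n_snps")
  total <- sum(n_snps_vec)
  n_reg <- length(records)

  # chromosome layout: cut at the first region boundary past snps_per_chrom
  chrom_id <- integer(n_reg)
  chrom <- 1L
  in_chrom <- 0L
  for (i in seq_len(n_reg)) {
    if (in_chrom >= config$snps_per_chrom) {
      chrom <- chrom + 1L
      in_chrom <- 0L
    }
    chrom_id[i] <- chrom
    in_chrom <- in_chrom + n_snps_vec[i]
  }
  chrom_sizes <- as.integer(tapply(n_snps_vec, chrom_id, sum))

  pfb <- make_pfb(config$pfb, total)
  grid <- make_snp_grid(total, pfb = pfb, spacing_bp = config$spacing_bp,
                        chrom_sizes = chrom_sizes)

  snp_end <- cumsum(n_snps_vec)
  snp_start <- snp_end - n_snps_vec
  offset_in_chrom <- snp_start -
    c(0L, cumsum(chrom_sizes))[chrom_id]

  truth <- data.frame(
    chrom = sprintf("chr%d", chrom_id),
    start = offset_in_chrom * config$spacing_bp,
    end = (offset_in_chrom + n_snps_vec) * config$spacing_bp,
    name = sprintf("%s_%04d", vapply(records, `[[`, "", "label"), seq_len(n_reg)),
    copy_number = vapply(records, function(r) r$cn[which.max(r$frac)], 0L),
    loh = vapply(records, function(r)
      region_loh_status(region_spec(n_snps = r$n_snps, cn = r$cn,
                                    h1_copies = r$h1, fractions = r$frac,
                                    germline_loh = r$germ)), ""),
    subclones = vapply(records, function(r)
      format_subclones(r$cn, r$h1, r$frac), ""),
    n_snps = n_snps_vec,
    snp_start = snp_start,
    snp_end = snp_end,
    stringsAsFactors = FALSE)
  class(truth) <- c("cna_truth", "data.frame")

  di <- dna_index(truth)
  l <- draw_baseline_shift(di, config, contamination = contamination)

  normal_z <- sample_normal_genotypes(grid)
  w1 <- contamination
  base_lrr <- numeric(total)
  noiseless_baf <- numeric(total)
  model <- config$lrr_model
  for (i in seq_len(n_reg)) {
    r <- records[[i]]
    idx <- (snp_start[i] + 1L):snp_end[i]
    spec <- region_spec(n_snps = r$n_snps, snp_start = snp_start[i],
                        cn = r$cn, h1_copies = r$h1, fractions = r$frac,
                        germline_loh = r$germ, label = r$label)
    gm <- assign_region_genotypes(spec, normal_z[idx], pfb = grid$pfb[idx])
    normal_z[idx] <- gm$z[, 1L]  # germline-LOH regions resample the normal genome
    w <- matrix(rep(c(w1, (1 - w1) * r$frac), each = r$n_snps), nrow = r$n_snps)
    rr <- draw_lrr_levels(gm$x, model)
    base_lrr[idx] <- rowSums(w * rr)
    denom <- rowSums(w * gm$x)
    noiseless_baf[idx] <- ifelse(denom == 0, NA_real_, rowSums(w * gm$z) / denom)
  }
  ci <- arma_series(config$arma, total)
  if (!is.null(config$waves)) ci <- ci + arma_series(config$waves, total)
  lrr <- base_lrr + l + ci
  baf <- add_baf_noise(noiseless_baf, config$baf_noise)

  structure(list(grid = grid, lrr = lrr, baf = baf, truth = truth,
                 contamination = contamination, baseline_shift = l,
                 dna_index = di, preset = preset_name, config = config),
            class = "cna_sample")
}

#' Generate one sample from a pattern preset
#'
#' Realizes the preset's archetype menu as a full synthetic sample: the
#' fixed SNP budgets are split into 205-280 fragments with lengths from
#' \{10, 20, 40, 80, 160\} SNPs, fragments are laid down in shuffled order
#' across synthetic chromosomes, germline genotypes and per-region clone
#' genotypes are drawn, and LRR/BAF signals are synthesized with the
#' configured noise, baseline shift and autocorrelated bias.
#'
#' @param preset a [pattern_preset()] or preset name.
#' @param contamination normal-cell fraction; defaults to the config value.
#' @param seed integer seed driving every random choice of the sample.
#' @param config a [sample_config()].
#' @return An object of class `cna_sample`: list with `grid`, `lrr`, `baf`,
#'   `truth`, `contamination`, `baseline_shift`, `dna_index`.
#' @export
build_pattern <- function(preset, contamination = NULL, seed = NULL,
                          config = sample_config()) {
  if (is.character(preset)) preset <- pattern_preset(preset)
  stopifnot(inherits(preset, "pattern_preset"))
  contamination <- contamination %||% config$contamination
  with_seed(seed, {
    budgets <- vapply(preset$archetypes, `[[`, 0L, "budget")
    # aim inside [min_fragments, max_fragments] with margin for rounding
    n_total <- sample(seq(preset$min_fragments + 10L,
                          preset$max_fragments - 10L), 1L)
    counts <- allocate_counts(budgets, n_total, preset$lengths)
    records <- list()
    for (a in seq_along(preset$archetypes)) {
      ar <- preset$archetypes[[a]]
      lens <- partition_lengths(ar$budget, counts[a], preset$lengths)
      for (len in lens)
        records[[length(records) + 1L]] <-
          list(label = ar$label, n_snps = len, cn = ar$cn, h1 = ar$h1,
               frac = ar$frac, germ = ar$germ)
    }
    records <- records[sample.int(length(records))]
    assemble_sample(records, contamination, config, preset_name = preset$name)
  })
}

#' Generate a replicate set
#'
#' Per-replicate seeds are derived deterministically from `base_seed`, so a
#' replicate set is reproducible as a whole while replicates differ in
#' fragment counts, lengths and placement.
#'
#' @param preset a [pattern_preset()] or name.
#' @param contamination normal-cell fraction.
#' @param n_reps number of replicates.
#' @param base_seed integer seed for the whole set.
#' @param config a [sample_config()].
#' @return list of `cna_sample` objects.
#' @export
generate_replicates <- function(preset, contamination = NULL, n_reps = 100L,
                                base_seed = 1L, config = sample_config()) {
  if (!is_count(n_reps) || n_reps < 1) stop_("n_reps must be >= 1")
  lapply(seq_len(n_reps), function(i)
    build_pattern(preset, contamination, seed = derive_seed(base_seed, i),
                  config = config))
}

#' DNA index of a truth annotation
#'
#' Half of the SNP-length-weighted mean copy number of the tumour cell
#' population (subclone-fraction-weighted within regions).  Normal-cell
#' contamination is excluded: the index describes the tumour genome itself.
#'
#' @param truth a `cna_truth` data.frame or a `cna_sample`.
#' @return numeric DNA index (1 for a fully diploid genome).
#' @export
dna_index <- function(truth) {
  truth <- as_truth(truth)
  if (nrow(truth) == 0L) stop_("dna_index: empty truth")
  clones <- parse_subclones(truth$subclones)
  eff_cn <- vapply(clones, function(cl) sum(cl$cn * cl$frac), 0)
  sum(truth$n_snps * eff_cn) / sum(truth$n_snps) / 2
}

#' Draw the sample-wide LRR baseline shift
#'
#' `l ~ N(-slope * (DI_eff - 1), sd)` where
#' `DI_eff = (1 - w1) * DI + w1` is the DNA index of the cell mixture
#' actually hybridized (contamination pulls the effective ploidy towards
#' diploid).  A diploid mixture (`DI_eff = 1`) is anchored at zero shift.
#'
#' @param dna_index tumour DNA index (contamination-free).
#' @param config a [sample_config()] supplying `shift_law` and, by default,
#'   the contamination.
#' @param contamination optional override of `config$contamination`.
#' @param seed optional integer seed.
#' @return numeric shift `l`.
#' @export
draw_baseline_shift <- function(dna_index, config = sample_config(),
                                contamination = NULL, seed = NULL) {
  if (dna_index <= 0) stop_("draw_baseline_shift: dna_index must be > 0")
  w1 <- contamination %||% config$contamination
  di_eff <- (1 - w1) * dna_index + w1
  with_seed(seed, stats::rnorm(1L, -config$shift_law[["slope"]] * (di_eff - 1),
                               config$shift_law[["sd"]]))
}

#' @export
print.cna_sample <- function(x, ...) {
  cat(sprintf("<cna_sample> %d SNPs on %d chromosomes, %d truth regions\n",
              nrow(x$grid), length(unique(x$grid$chrom)), nrow(x$truth)))
  cat(sprintf("  preset: %s | contamination: %.2f | DNA index: %.3f | shift: %.3f\n",
              x$preset, x$contamination, x$dna_index, x$baseline_shift))
  invisible(x)
}
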