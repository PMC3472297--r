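# Independent oracles used across the suite.  These re-derive expected
# behaviour from the model equations by enumeration / naive computation and
# deliberately share no code with the package internals.

# --- genotype coherence ------------------------------------------------------

# Admissibility of a genotype matrix, checked declaratively:
#  * 0 <= z <= x, normal z in {0,1,2}
#  * homozygous normal loci force every clone homozygous for the same allele
#  * heterozygous loci are pairwise equal or jointly mirrored across clones
oracle_admissible <- function(z, x) {
  if (any(z < 0) || any(z > x)) return(FALSE)
  z1 <- z[, 1]
  if (any(!z1 %in% 0:2)) return(FALSE)
  for (j in seq_len(ncol(z) - 1) + 1) {
    if (any(z[z1 == 0, j] != 0)) return(FALSE)
    if (any(z[z1 == 2, j] != x[z1 == 2, j])) return(FALSE)
  }
  het <- which(z1 == 1)
  if (length(het) > 1) {
    for (a in seq_along(het)) for (b in seq_along(het)) {
      if (a == b) next
      s <- het[a]; t <- het[b]
      same <- all(z[t, -1] == z[s, -1])
      mirr <- all(z[t, -1] == x[t, -1] - z[s, -1])
      if (!(same || mirr)) return(FALSE)
    }
  }
  TRUE
}

# Brute-force enumeration of every admissible tumour-clone assignment for a
# fixed normal genotype vector z1 and per-clone copy numbers x_clones.
# Returns a character set: each element encodes one admissible z matrix
# (clone columns only), SNPs x clones flattened row-wise.
oracle_enumerate <- function(z1, x_clones) {
  n <- length(z1)
  k <- length(x_clones)
  per_snp <- lapply(seq_len(n), function(i) {
    opts <- lapply(x_clones, function(xj) {
      if (z1[i] == 0) 0L else if (z1[i] == 2) xj else 0:xj
    })
    as.matrix(expand.grid(opts))
  })
  combo <- expand.grid(lapply(per_snp, function(m) seq_len(nrow(m))))
  keys <- character(0)
  x <- cbind(2L, matrix(rep(x_clones, each = n), nrow = n))
  for (r in seq_len(nrow(combo))) {
    zc <- do.call(rbind, lapply(seq_len(n), function(i)
      per_snp[[i]][combo[r, i], , drop = TRUE]))
    zc <- matrix(as.integer(zc), nrow = n)
    if (oracle_admissible(cbind(z1, zc), x))
      keys <- c(keys, paste(t(zc), collapse = ","))
  }
  unique(keys)
}

genotype_key <- function(z_clones) paste(t(z_clones), collapse = ",")

# --- evaluation --------------------------------------------------------------

# Naive all-pairs recall: double loop over truth regions and calls.
oracle_recall <- function(truth, calls, min_overlap = 0.5, require_loh = FALSE) {
  keep_t <- !(truth$copy_number == 2 & truth$loh == "none" &
                !grepl("|", truth$subclones, fixed = TRUE))
  truth <- truth[keep_t, , drop = FALSE]
  keep_c <- !(calls$copy_number == 2 & !calls$loh %in% c("somatic", "germline"))
  calls <- calls[keep_c, , drop = FALSE]
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    len <- truth$end[i] - truth$start[i]
    for (j in seq_len(nrow(calls))) {
      if (calls$chrom[j] != truth$chrom[i]) next
      if (calls$copy_number[j] != truth$copy_number[i]) next
      if (require_loh) {
        t_loh <- truth$loh[i] %in% c("somatic", "germline")
        c_loh <- calls$loh[j] %in% c("somatic", "germline")
        if (t_loh != c_loh) next
      }
      ov <- min(truth$end[i], calls$end[j]) - max(truth$start[i], calls$start[j])
      if (ov >= min_overlap * len) { hit[i] <- TRUE; break }
    }
  }
  list(truth = truth, recalled = hit)
}

# Naive wrong-copy-number FDR: max-overlap matching, leftmost tie-break.
oracle_fdr <- function(truth, calls) {
  keep_t <- !(truth$copy_number == 2 & truth$loh == "none" &
                !grepl("|", truth$subclones, fixed = TRUE))
  truth <- truth[keep_t, , drop = FALSE]
  keep_c <- !(calls$copy_number == 2 & !calls$loh %in% c("somatic", "germline"))
  calls <- calls[keep_c, , drop = FALSE]
  if (nrow(calls) == 0) return(0)
  wrong <- 0
  for (j in seq_len(nrow(calls))) {
    best <- 0; best_i <- NA
    for (i in seq_len(nrow(truth))) {
      if (truth$chrom[i] != calls$chrom[j]) next
      ov <- min(truth$end[i], calls$end[j]) - max(truth$start[i], calls$start[j])
      if (ov > best) { best <- ov; best_i <- i }
    }
    if (is.na(best_i) || truth$copy_number[best_i] != calls$copy_number[j])
      wrong <- wrong + 1
  }
  wrong / nrow(calls)
}

# --- fixtures ----------------------------------------------------------------

make_truth_df <- function(chrom, start, end, copy_number,
                          loh = "none", subclones = NULL, n_snps = NULL) {
  n <- length(start)
  if (is.null(subclones)) subclones <- sprintf("%d:%d:1", copy_number,
                                               ceiling(copy_number / 2))
  if (is.null(n_snps)) n_snps <- as.integer((end - start) / 5000)
  out <- data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                    name = sprintf("r%d", seq_len(n)),
                    copy_number = as.integer(copy_number),
                    loh = rep_len(loh, n),
                    subclones = rep_len(subclones, n),
                    n_snps = n_snps,
                    snp_start = as.integer(start / 5000),
                    snp_end = as.integer(end / 5000),
                    stringsAsFactors = FALSE)
  class(out) <- c("cna_truth", "data.frame")
  out
}

make_calls_df <- function(chrom, start, end, copy_number, loh = "unspecified") {
  out <- data.frame(chrom = rep_len(chrom, length(start)), start = start,
                    end = end, copy_number = as.integer(copy_number),
                    loh = rep_len(loh, length(start)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cna_calls", "data.frame")
  out
}

# genotype matrix built directly (bypassing the generator) for signal tests
make_gm <- function(x, z) {
  structure(list(x = x, z = z, phase = rep(TRUE, nrow(x)), label = "fixture"),
            class = "genotype_matrix")
}

fast_config <- function(...) {
  sample_config(arma = arma_model(), ...)
}

zero_noise_config <- function(...) {
  sample_config(
    lrr_model = lrr_model(sigma = 0),
    arma = arma_model(),
    baf_noise = baf_noise_model(sigma_he = 0, sigma_ho = 0, pi_extreme = 1),
    shift_law = c(slope = 0.6, sd = 0), ...)
}
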