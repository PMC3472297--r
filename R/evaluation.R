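# Benchmark harness: overlap-based recall and the wrong-copy-number FDR
# approximation.  All interval arithmetic is in basepairs on 0-based
# half-open intervals.

bp_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# A call "claims LOH" when its loh field is somatic or germline; truth
# regions claim LOH when their status is not "none".  Germline vs somatic is
# deliberately not distinguished at matching time.
claims_loh <- function(loh) loh %in% c("somatic", "germline")

is_diploid_het_truth <- function(truth) {
  single <- !grepl("|", truth$subclones, fixed = TRUE)
  single & truth$copy_number == 2L & truth$loh == "none"
}

is_diploid_het_call <- function(calls) {
  calls$copy_number == 2L & !claims_loh(calls$loh)
}

#' Is a truth region recalled by a call set?
#'
#' A region counts as recalled when a single call with the same copy number
#' (and, if `require_loh`, the same LOH presence/absence, regardless of
#' germline vs somatic) overlaps at least `min_overlap` of the region's
#' basepair length.  Multiple partial calls are never pooled.
#'
#' @param truth_region one-row `cna_truth` data.frame (or list with fields
#'   `chrom`, `start`, `end`, `copy_number`, `loh`).
#' @param calls a `cna_calls` data.frame.
#' @param min_overlap minimum overlapped fraction of the region length;
#'   "at least half" by default (a tie at exactly 0.5 counts).
#' @param require_loh also require matching LOH presence/absence.
#' @return logical.
#' @export
region_recalled <- function(truth_region, calls, min_overlap = 0.5,
                            require_loh = FALSE) {
  if (min_overlap <= 0 || min_overlap > 1)
    stop_("region_recalled: min_overlap must lie in (0, 1]")
  tr <- as.list(truth_region)
  if (!nrow(calls)) return(FALSE)
  cand <- calls$chrom == tr$chrom & calls$copy_number == tr$copy_number
  if (require_loh)
    cand <- cand & (claims_loh(calls$loh) == claims_loh(tr$loh))
  if (!any(cand)) return(FALSE)
  ov <- bp_overlap(tr$start, tr$end, calls$start[cand], calls$end[cand])
  any(ov >= min_overlap * (tr$end - tr$start))
}

#' Recall table over samples
#'
#' Computes overlap-based recall rates aggregated over replicate samples,
#' broken down by the requested grouping variables.  Diploid-heterozygous
#' truth regions and diploid-heterozygous calls are excluded before
#' matching.  Empty cells are reported with `recall = NA`, not 0.
#'
#' @param truth_sets list of `cna_truth` data.frames (one per sample).
#' @param call_sets list of `cna_calls` data.frames, paired with
#'   `truth_sets`.
#' @param contamination numeric vector, the contamination level per sample
#'   (recycled if scalar).
#' @param by grouping variables, a subset of
#'   `c("contamination", "copy_number", "length", "loh")`; `length` groups
#'   by region length in SNPs.
#' @param min_overlap,require_loh as in [region_recalled()].
#' @return data.frame of class `recall_table` with the grouping columns plus
#'   `n_truth`, `n_recalled`, `recall`.
#' @export
recall_table <- function(truth_sets, call_sets, contamination = NA_real_,
                         by = c("contamination", "copy_number"),
                         min_overlap = 0.5, require_loh = FALSE) {
  if (inherits(truth_sets, "cna_truth")) truth_sets <- list(truth_sets)
  if (is.data.frame(call_sets)) call_sets <- list(call_sets)
  if (length(truth_sets) != length(call_sets))
    stop_("recall_table: truth and calls must be paired per sample")
  by <- match.arg(by, c("contamination", "copy_number", "length", "loh"),
                  several.ok = TRUE)
  contamination <- rep_len(contamination, length(truth_sets))
  rows <- list()
  for (s in seq_along(truth_sets)) {
    truth <- truth_sets[[s]]
    truth <- truth[!is_diploid_het_truth(truth), , drop = FALSE]
    calls <- call_sets[[s]]
    calls <- calls[!is_diploid_het_call(calls), , drop = FALSE]
    if (!nrow(truth)) next
    rec <- vapply(seq_len(nrow(truth)), function(i)
      region_recalled(truth[i, ], calls, min_overlap, require_loh), NA)
    rows[[length(rows) + 1L]] <- data.frame(
      contamination = contamination[s],
      copy_number = truth$copy_number,
      length = truth$n_snps,
      loh = claims_loh(truth$loh),
      recalled = rec)
  }
  if (!length(rows)) stop_("recall_table: no evaluable truth regions")
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(df$recalled, by = df[by],
                          FUN = function(v) c(n = length(v), k = sum(v)))
  out <- cbind(agg[by], n_truth = agg$x[, "n"], n_recalled = agg$x[, "k"])
  out$recall <- ifelse(out$n_truth > 0, out$n_recalled / out$n_truth, NA_real_)
  class(out) <- c("recall_table", "data.frame")
  out
}

#' Wrong-copy-number FDR matrix
#'
#' Each non-diploid call is matched to the truth region with which it shares
#' the largest basepair overlap (ties broken by the leftmost truth region);
#' a call is wrong when its copy number differs from that region's.  The
#' matrix gives, per (called, true) copy-number pair, the fraction of all
#' calls that are wrong with that pair; calls overlapping no truth region
#' are tallied under the true-CN column `"none"`.  The total FDR is the sum
#' of the off-diagonal mass, i.e. the overall wrong-call fraction.  This is
#' an approximation suited to densely altered genomes: methods with finer
#' breakpoint detection naturally score higher, so values are not comparable
#' across callers.
#'
#' @param truth a `cna_truth` data.frame.
#' @param calls a `cna_calls` data.frame.
#' @return list of class `fdr_matrix` with `matrix` (called x true wrong
#'   fractions), `total_fdr` and `n_calls`.
#' @export
fdr_matrix <- function(truth, calls) {
  truth <- as_truth(truth)
  truth <- truth[!is_diploid_het_truth(truth), , drop = FALSE]
  calls <- calls[!is_diploid_het_call(calls), , drop = FALSE]
  n_calls <- nrow(calls)
  called_levels <- sort(unique(calls$copy_number))
  true_levels <- sort(unique(truth$copy_number))
  m <- matrix(0, nrow = length(called_levels), ncol = length(true_levels) + 1L,
              dimnames = list(called = as.character(called_levels),
                              true = c(as.character(true_levels), "none")))
  if (n_calls == 0L)
    return(structure(list(matrix = m, total_fdr = 0, n_calls = 0L),
                     class = "fdr_matrix"))
  for (i in seq_len(n_calls)) {
    same <- truth$chrom == calls$chrom[i]
    ov <- numeric(nrow(truth))
    ov[same] <- bp_overlap(calls$start[i], calls$end[i],
                           truth$start[same], truth$end[same])
    if (!any(ov > 0)) {
      m[as.character(calls$copy_number[i]), "none"] <-
        m[as.character(calls$copy_number[i]), "none"] + 1
      next
    }
    j <- which(ov == max(ov))[1L]  # truth rows are in genome order: leftmost tie-break
    if (calls$copy_number[i] != truth$copy_number[j])
      m[as.character(calls$copy_number[i]), as.character(truth$copy_number[j])] <-
        m[as.character(calls$copy_number[i]), as.character(truth$copy_number[j])] + 1
  }
  m <- m / n_calls
  structure(list(matrix = m, total_fdr = sum(m), n_calls = n_calls),
            class = "fdr_matrix")
}

#' Estimate the coefficient of contraction
#'
#' Normal-cell contamination shrinks LRR amplitudes linearly: per sample,
#' the observed per-region LRR means (baseline shift removed) are regressed
#' on their pure-tumour expectations, giving the contraction coefficient
#' `q`; `q` is then fitted against tumour purity `1 - w1` across samples.
#' Under the linear mixing model `q = 1 - w1` exactly, so the purity fit has
#' slope 1 through the origin.
#'
#' @param samples list of `cna_sample` objects spanning at least two
#'   distinct contamination levels.
#' @return list of class `contraction_fit`: per-sample `q` and `purity`,
#'   plus `slope`, `intercept` and `r_squared` of the q-vs-purity fit.
#' @export
estimate_contraction <- function(samples) {
  if (length(samples) < 2L)
    stop_("estimate_contraction: need at least two samples")
  q <- purity <- numeric(length(samples))
  for (s in seq_along(samples)) {
    smp <- samples[[s]]
    truth <- smp$truth
    mu <- smp$config$lrr_model$mu
    clones <- parse_subclones(truth$subclones)
    expected <- vapply(clones, function(cl)
      sum(cl$frac * lookup_cn(mu, cl$cn, "mu")), 0)
    observed <- vapply(seq_len(nrow(truth)), function(i)
      mean(smp$lrr[(truth$snp_start[i] + 1L):truth$snp_end[i]]), 0) -
      smp$baseline_shift
    if (stats::var(expected) == 0)
      stop_("estimate_contraction: degenerate regression (all regions diploid)")
    fit <- stats::lm(observed ~ expected)
    q[s] <- unname(stats::coef(fit)[2L])
    purity[s] <- 1 - smp$contamination
  }
  if (length(unique(purity)) < 2L)
    stop_("estimate_contraction: need at least two distinct contamination levels")
  pf <- stats::lm(q ~ purity)
  # R^2 computed directly: summary.lm warns on the exact zero-noise fit
  r2 <- 1 - sum(stats::residuals(pf)^2) / sum((q - mean(q))^2)
  structure(list(q = q, purity = purity,
                 slope = unname(stats::coef(pf)[2L]),
                 intercept = unname(stats::coef(pf)[1L]),
                 r_squared = r2),
            class = "contraction_fit")
}

#' @export
print.fdr_matrix <- function(x, ...) {
  cat(sprintf("<fdr_matrix> %d calls, total FDR %.3f\n", x$n_calls, x$total_fdr))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @export
print.contraction_fit <- function(x, ...) {
  cat(sprintf("<contraction_fit> q ~ purity: slope %.4f, intercept %.4f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
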