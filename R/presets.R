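# Pattern presets: fixed per-replicate SNP budgets over region archetypes.
#
# Each archetype fixes the per-clone copy numbers, the allelic-imbalance
# descriptor (copies of parental haplotype 1), subclone fractions and the
# germline-LOH flag; the budget is the exact number of SNPs the archetype
# occupies in every replicate.  Budgets are chosen so that the
# SNP-length-weighted DNA index and the labelled composition fraction of
# each preset equal its published-style targets exactly; per-replicate
# randomness lies in how budgets split into fragments of 10-160 SNPs and in
# placement order.

arch <- function(label, budget, cn, h1 = NULL, frac = NULL, germ = FALSE) {
  if (is.null(h1)) h1 <- as.integer(ceiling(cn / 2))
  if (is.null(frac)) frac <- rep(1 / length(cn), length(cn))
  list(label = label, budget = as.integer(budget), cn = as.integer(cn),
       h1 = as.integer(h1), frac = frac, germ = germ)
}

preset_defs <- function() {
  list(
    near_diploid = list(
      dna_index = 1.03, composition = c(cn2_het = 45.4),
      archetypes = list(
        arch("cn2het", 5450, 2, 1),
        arch("cn2loh", 1440, 2, 2),
        arch("germ",    600, 2, 1, germ = TRUE),
        arch("cn1",    2230, 1, 1),
        arch("cn3",    1730, 3, 2),
        arch("cn4",     430, 4, 2),
        arch("cn5",     120, 5, 3))),
    near_triploid = list(
      dna_index = 1.32, composition = c(cn3 = 40.3),
      archetypes = list(
        arch("cn3_21", 4040, 3, 2),
        arch("cn3_30",  800, 3, 3),
        arch("cn2het", 3740, 2, 1),
        arch("cn2loh",  600, 2, 2),
        arch("germ",    400, 2, 1, germ = TRUE),
        arch("cn1",     800, 1, 1),
        arch("cn4_22",  820, 4, 2),
        arch("cn4_31",  400, 4, 3),
        arch("cn5_32",  400, 5, 3))),
    near_tetraploid = list(
      dna_index = 1.57, composition = c(cn4 = 38.3),
      archetypes = list(
        arch("cn4_22", 3000, 4, 2),
        arch("cn4_31", 1100, 4, 3),
        arch("cn4_40",  500, 4, 4),
        arch("cn2het", 2620, 2, 1),
        arch("cn2loh",  500, 2, 2),
        arch("germ",    400, 2, 1, germ = TRUE),
        arch("cn1",     600, 1, 1),
        arch("cn3_21", 1780, 3, 2),
        arch("cn3_30",  600, 3, 3),
        arch("cn5_32",  600, 5, 3),
        arch("cn5_41",  300, 5, 4))),
    loh_enriched = list(
      dna_index = 1.31, composition = c(loh = 40.1),
      archetypes = list(
        arch("germ",   1200, 2, 1, germ = TRUE),
        arch("cn1",    1400, 1, 1),
        arch("cn2loh", 1500, 2, 2),
        arch("cn3_30",  510, 3, 3),
        arch("cn4_40",  200, 4, 4),
        arch("cn2het", 2500, 2, 1),
        arch("cn3_21", 1950, 3, 2),
        arch("cn4_22", 1500, 4, 2),
        arch("cn4_31",  740, 4, 3),
        arch("cn5_32",  500, 5, 3))),
    complex = list(
      dna_index = 1.39, composition = c(complex = 47.6),
      archetypes = list(
        arch("comp_del_dup",      1500, c(1, 2), c(1, 1), c(0.5, 0.5)),
        arch("comp_dip_gain",     1500, c(2, 4), c(1, 3), c(0.5, 0.5)),
        arch("comp_del_dup_trip", 2000, c(0, 3, 4), c(0, 2, 3), c(0.25, 0.5, 0.25)),
        arch("comp_gain_gain",     710, c(3, 5), c(2, 3), c(0.5, 0.5)),
        arch("cn2het", 1900, 2, 1),
        arch("cn1",     500, 1, 1),
        arch("cn3_21", 1590, 3, 2),
        arch("cn4_22", 1800, 4, 2),
        arch("cn5_32",  500, 5, 3)))
  )
}

#' Pattern presets for characteristic tumour alteration profiles
#'
#' Five presets emulate characteristic genome-wide alteration patterns:
#' `near_diploid` (DNA index 1.03, 45.4% of the genome diploid
#' heterozygous), `near_triploid` (1.32, 40.3% CN3), `near_tetraploid`
#' (1.57, 38.3% CN4), `loh_enriched` (1.31, 40.1% LOH) and `complex`
#' (1.39, 47.6% of the genome in multi-subclone regions).  Every replicate
#' spans 12,000 SNPs split into 205-280 fragments whose lengths are drawn
#' from \{10, 20, 40, 80, 160\} SNPs.
#'
#' @param name preset name; see [list_presets()].
#' @return An object of class `pattern_preset` with the archetype menu and
#'   its composition / DNA-index targets.
#' @export
pattern_preset <- function(name) {
  defs <- preset_defs()
  if (!name %in% names(defs))
    stop_("unknown preset '%s'; valid presets: %s", name,
          paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  structure(list(name = name, archetypes = d$archetypes,
                 target_dna_index = d$dna_index,
                 target_composition = d$composition,
                 genome_snps = sum(vapply(d$archetypes, `[[`, 0L, "budget")),
                 lengths = c(10L, 20L, 40L, 80L, 160L),
                 min_fragments = 205L, max_fragments = 280L),
            class = "pattern_preset")
}

#' @rdname pattern_preset
#' @export
list_presets <- function() names(preset_defs())

# Split `budget` SNPs into `n_parts` fragment lengths drawn from `lengths`,
# summing exactly.  Feasibility bookkeeping by dynamic programming over the
# number of remaining parts and the remaining budget (in units of the
# shortest length); each part is drawn uniformly among currently feasible
# lengths.
partition_lengths <- function(budget, n_parts, lengths = c(10L, 20L, 40L, 80L, 160L)) {
  unit <- min(lengths)
  if (budget %% unit != 0L) stop_("budget %d is not a multiple of %d", budget, unit)
  mults <- as.integer(lengths / unit)
  M <- budget %/% unit
  if (M < n_parts * min(mults) || M > n_parts * max(mults))
    stop_("cannot split %d SNPs into %d fragments", budget, n_parts)
  # rep[k + 1, R + 1]: R units achievable with k parts
  rep_tab <- matrix(FALSE, nrow = n_parts + 1L, ncol = M + 1L)
  rep_tab[1L, 1L] <- TRUE
  for (k in seq_len(n_parts)) {
    prev <- rep_tab[k, ]
    cur <- logical(M + 1L)
    for (v in mults) {
      if (v < M + 1L) cur[(v + 1L):(M + 1L)] <-
          cur[(v + 1L):(M + 1L)] | prev[seq_len(M + 1L - v)]
    }
    rep_tab[k + 1L, ] <- cur
  }
  if (!rep_tab[n_parts + 1L, M + 1L])
    stop_("cannot split %d SNPs into %d fragments", budget, n_parts)
  out <- integer(n_parts)
  R <- M
  for (i in n_parts:1L) {
    ok <- mults[mults <= R]
    ok <- ok[rep_tab[i, R - ok + 1L]]
    v <- if (length(ok) == 1L) ok else sample(ok, 1L)
    out[i] <- v
    R <- R - v
  }
  out * unit
}

# Deterministically allocate a total fragment count N across archetypes,
# proportionally to their SNP budgets and within each archetype's feasible
# range.
allocate_counts <- function(budgets, n_total, lengths = c(10L, 20L, 40L, 80L, 160L)) {
  lo <- ceiling(budgets / max(lengths))
  hi <- floor(budgets / min(lengths))
  raw <- n_total * budgets / sum(budgets)
  n <- pmin(pmax(round(raw), lo), hi)
  while (sum(n) > n_total) {
    cand <- which(n > lo)
    i <- cand[which.max(n[cand] - raw[cand])]
    n[i] <- n[i] - 1L
  }
  while (sum(n) < n_total) {
    cand <- which(n < hi)
    i <- cand[which.min(n[cand] - raw[cand])]
    n[i] <- n[i] + 1L
  }
  as.integer(n)
}

#' Composition summary of a truth annotation
#'
#' SNP-length-weighted genome fractions by category: per-copy-number shares
#' of single-clone regions (`cn0` ... `cn5`), the diploid-heterozygous share
#' (`cn2_het`), the share under LOH of either kind (`loh`) and the share in
#' multi-subclone regions (`complex`).
#'
#' @param truth a truth annotation (`cna_truth` data.frame) or a
#'   `cna_sample`.
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
truth_composition <- function(truth) {
  truth <- as_truth(truth)
  clones <- parse_subclones(truth$subclones)
  n <- truth$n_snps
  total <- sum(n)
  single <- vapply(clones, nrow, 0L) == 1L
  cn1st <- vapply(clones, function(cl) cl$cn[1L], 0)
  out <- c(vapply(0:5, function(k) sum(n[single & cn1st == k]), 0) / total,
           sum(n[single & cn1st == 2 & truth$loh == "none"]) / total,
           sum(n[truth$loh != "none"]) / total,
           sum(n[!single]) / total)
  names(out) <- c(paste0("cn", 0:5), "cn2_het", "loh", "complex")
  out
}
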