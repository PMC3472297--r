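#' Read a region scaffold
#'
#' A scaffold fixes the sequence of regions of a sample — typically derived
#' from segmentation output on a real tumour, making the generated data a
#' hybrid between synthetic and real.  Tab-separated columns with a header:
#' `length_snps` (integer), `cn` (comma-separated copy number per clone),
#' `ratio` (comma-separated `h1:h2` allelic split per clone, consistent with
#' `cn`), `germline_loh` (0/1) and optionally `fractions` (comma-separated
#' subclone fractions, default equal).
#'
#' @param path scaffold TSV path.
#' @return An object of class `cna_scaffold`: list of region records.
#' @export
read_scaffold <- function(path) {
  if (!file.exists(path)) stop_("read_scaffold: file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("length_snps", "cn", "ratio", "germline_loh")
  if (!all(need %in% names(tab)))
    stop_("read_scaffold: missing column(s): %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    len <- suppressWarnings(as.integer(tab$length_snps[i]))
    if (is.na(len) || len < 1L)
      stop_("read_scaffold: record %d: length_snps must be a positive integer", i)
    cn <- suppressWarnings(as.integer(strsplit(as.character(tab$cn[i]), ",")[[1]]))
    if (anyNA(cn) || any(cn < 0L))
      stop_("read_scaffold: record %d: malformed cn", i)
    ratio <- strsplit(as.character(tab$ratio[i]), ",")[[1]]
    if (length(ratio) != length(cn))
      stop_("read_scaffold: record %d: ratio count differs from clone count", i)
    h <- lapply(strsplit(ratio, ":", fixed = TRUE),
                function(p) suppressWarnings(as.integer(p)))
    if (any(lengths(h) != 2L) || anyNA(unlist(h)))
      stop_("read_scaffold: record %d: malformed ratio (expected 'a:b')", i)
    h1 <- vapply(h, `[[`, 0L, 1L)
    if (any(h1 + vapply(h, `[[`, 0L, 2L) != cn))
      stop_("read_scaffold: record %d: ratio does not sum to cn", i)
    frac <- if ("fractions" %in% names(tab) && nzchar(tab$fractions[i]) &&
                !is.na(tab$fractions[i]))
      as.numeric(strsplit(as.character(tab$fractions[i]), ",")[[1]])
    else rep(1 / length(cn), length(cn))
    if (length(frac) != length(cn) || abs(sum(frac) - 1) > 1e-6)
      stop_("read_scaffold: record %d: fractions must match clones and sum to 1", i)
    records[[i]] <- list(label = sprintf("scaffold_%d", i), n_snps = len,
                         cn = cn, h1 = h1, frac = frac,
                         germ = as.integer(tab$germline_loh[i]) == 1L)
  }
  structure(records, class = "cna_scaffold")
}

#' Generate a sample from a scaffold
#'
#' Regions are laid down in scaffold order (no shuffling: the scaffold
#' carries the real spatial distribution of rearrangements).  Genome-wide
#' options of the configuration apply: `waves` adds a second, longer-memory
#' autocorrelated component; `complexity` converts single-clone non-diploid
#' regions into 2-subclone variants with the given probability.
#'
#' @param scaffold a `cna_scaffold` (see [read_scaffold()]) or a list of
#'   records with fields `n_snps`, `cn`, `h1`, `frac`, `germ`.
#' @param contamination normal-cell fraction; defaults to the config value.
#' @param config a [sample_config()].
#' @param seed integer seed.
#' @return A `cna_sample` (see [build_pattern()]).
#' @export
build_from_scaffold <- function(scaffold, contamination = NULL,
                                config = sample_config(), seed = NULL) {
  contamination <- contamination %||% config$contamination
  records <- unclass(scaffold)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$n_snps) || r$n_snps < 1L)
      stop_("build_from_scaffold: malformed record %d", i)
    records[[i]]$label <- r$label %||% sprintf("scaffold_%d", i)
    records[[i]]$germ <- isTRUE(r$germ)
    if (is.null(r$h1)) records[[i]]$h1 <- as.integer(ceiling(r$cn / 2))
    if (is.null(r$frac)) records[[i]]$frac <- rep(1 / length(r$cn), length(r$cn))
  }
  with_seed(seed, {
    if (config$complexity > 0) {
      for (i in seq_along(records)) {
        r <- records[[i]]
        if (length(r$cn) == 1L && r$cn != 2L && !r$germ &&
            stats::runif(1L) < config$complexity) {
          records[[i]]$cn <- c(r$cn, 2L)
          records[[i]]$h1 <- c(r$h1, 1L)
          records[[i]]$frac <- c(0.7, 0.3)
          records[[i]]$label <- paste0(r$label, "_split")
        }
      }
    }
    assemble_sample(records, contamination, config, preset_name = "scaffold")
  })
}
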