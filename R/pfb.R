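#' Population B allele frequency sources
#'
#' Five ways of assigning per-SNP population B allele frequencies (PFBs):
#' \describe{
#'   \item{`packaged_empirical`}{a shipped synthetic stand-in for real array
#'     PFB distributions: point masses at 0 and 1 plus a U-shaped beta
#'     component.  It approximates the shape of Illumina array PFB tables
#'     without shipping external data; supply a real `.pfb` via `kind =
#'     "file"` for exact replication.}
#'   \item{`uniform`}{`U(0, 1)`.}
#'   \item{`constant`}{a fixed value; 0.5 maximizes genotype information.}
#'   \item{`three_peak`}{point masses at 0 and 1 plus a narrow Gaussian at
#'     0.5, approximating the three-peak shape of human-genome PFBs.}
#'   \item{`file`}{values read from a PennCNV-dialect `.pfb` file.}
#' }
#'
#' @param kind one of the five source kinds above.
#' @param constant_value value used by `kind = "constant"`.
#' @param peak_weights three weights (0, 0.5, 1 peaks) for `three_peak`;
#'   normalized to sum 1.
#' @param peak_sd standard deviation of the central 0.5 peak.
#' @param path `.pfb` file path for `kind = "file"`.
#' @return An object of class `pfb_source`.
#' @export
pfb_source <- function(kind = c("packaged_empirical", "uniform", "constant",
                                "three_peak", "file"),
                       constant_value = 0.5,
                       peak_weights = c(0.35, 0.30, 0.35),
                       peak_sd = 0.02,
                       path = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant" &&
      (!is.numeric(constant_value) || constant_value < 0 || constant_value > 1))
    stop_("pfb_source: constant_value must lie in [0, 1]")
  if (kind == "three_peak") {
    if (length(peak_weights) != 3L || any(peak_weights < 0) || sum(peak_weights) <= 0)
      stop_("pfb_source: peak_weights must be three non-negative values")
    peak_weights <- peak_weights / sum(peak_weights)
  }
  if (kind == "file" && is.null(path))
    stop_("pfb_source: kind = 'file' requires a path")
  structure(list(kind = kind, constant_value = constant_value,
                 peak_weights = peak_weights, peak_sd = peak_sd, path = path),
            class = "pfb_source")
}

#' Draw a PFB vector from a source
#'
#' @param source a [pfb_source()].
#' @param n number of SNPs.
#' @param seed optional integer seed (the ambient RNG stream is used when
#'   `NULL`).
#' @return numeric vector of length `n`, all values in `[0, 1]`.
#' @export
make_pfb <- function(source, n, seed = NULL) {
  stopifnot(inherits(source, "pfb_source"))
  if (!is_count(n) || n < 1) stop_("make_pfb: n must be a positive integer")
  with_seed(seed, switch(
    source$kind,
    constant = rep(source$constant_value, n),
    uniform = stats::runif(n),
    three_peak = {
      comp <- sample.int(3L, n, replace = TRUE, prob = source$peak_weights)
      out <- numeric(n)
      out[comp == 1L] <- 0
      out[comp == 3L] <- 1
      mid <- comp == 2L
      out[mid] <- pmin(pmax(stats::rnorm(sum(mid), 0.5, source$peak_sd), 0), 1)
      out
    },
    packaged_empirical = {
      # synthetic stand-in: 12% exact 0, 12% exact 1, rest U-shaped beta
      comp <- sample.int(3L, n, replace = TRUE, prob = c(0.12, 0.76, 0.12))
      out <- numeric(n)
      out[comp == 3L] <- 1
      mid <- comp == 2L
      out[mid] <- stats::rbeta(sum(mid), 0.6, 0.6)
      out
    },
    file = {
      tab <- read_pfb(source$path)
      v <- tab$pfb
      if (length(v) >= n) v[seq_len(n)] else sample(v, n, replace = TRUE)
    }))
}

#' Read a PennCNV-dialect .pfb file
#'
#' Expected layout: a header row followed by tab-separated columns
#' `Name  Chr  Position  PFB`.
#'
#' @param path file path.
#' @return data.frame with columns `probe_name`, `chrom`, `position`, `pfb`.
#' @export
read_pfb <- function(path) {
  if (!file.exists(path)) stop_("read_pfb: file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_("read_pfb: %s is empty", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad))
    stop_("read_pfb: malformed record at line %d of %s", bad[1L] + 1L, path)
  pfb <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  nn <- which(is.na(pfb) | pfb < 0 | pfb > 1)
  if (length(nn))
    stop_("read_pfb: invalid PFB value at line %d of %s", nn[1L] + 1L, path)
  data.frame(probe_name = vapply(parts, `[[`, "", 1L),
             chrom = vapply(parts, `[[`, "", 2L),
             position = as.integer(vapply(parts, `[[`, "", 3L)),
             pfb = pfb, stringsAsFactors = FALSE)
}

#' Write a PennCNV-dialect .pfb file
#'
#' Values are printed with full double precision so that a write/read
#' round-trip returns identical values.
#'
#' @param grid a [snp_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfb <- function(grid, path) {
  stopifnot(inherits(grid, "snp_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Name\tChr\tPosition\tPFB", con)
  writeLines(sprintf("%s\t%s\t%d\t%.17g", grid$probe_name, grid$chrom,
                     grid$position, grid$pfb), con)
  invisible(path)
}
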