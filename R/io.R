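#' Write a per-SNP signal table
#'
#' Tab-separated table in the Illumina final-report dialect consumed by
#' CNA/LOH callers: header `Name  Chr  Position  Log R Ratio  B Allele
#' Freq`, one row per SNP in genome order, signals printed with 4 decimals.
#' Undefined BAF values (total copy number zero) are written as `NaN`.
#'
#' @param grid a [snp_grid()].
#' @param track list with numeric `lrr` and `baf` vectors of the grid's
#'   length (a `cna_sample` is also accepted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(grid, track = NULL, path) {
  if (inherits(grid, "cna_sample")) {
    track <- grid
    grid <- track$grid
  }
  stopifnot(inherits(grid, "snp_grid"))
  lrr <- track$lrr; baf <- track$baf
  if (length(lrr) != nrow(grid) || length(baf) != nrow(grid))
    stop_("write_signal_table: track length does not match the grid")
  num <- function(x) ifelse(is.na(x), "NaN", sprintf("%.4f", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Name\tChr\tPosition\tLog R Ratio\tB Allele Freq", con)
  writeLines(paste(grid$probe_name, grid$chrom, grid$position,
                   num(lrr), num(baf), sep = "\t"), con)
  invisible(path)
}

#' Read a per-SNP signal table
#'
#' @param path file written by [write_signal_table()].
#' @return list with `grid` (a [snp_grid()]) and numeric `lrr`, `baf`.
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) stop_("read_signal_table: file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN"))
  need <- c("Name", "Chr", "Position", "Log R Ratio", "B Allele Freq")
  if (!all(need %in% names(tab)))
    stop_("read_signal_table: missing column(s): %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  grid <- snp_grid(tab$Name, tab$Chr, tab$Position, rep(0.5, nrow(tab)))
  list(grid = grid, lrr = as.numeric(tab$`Log R Ratio`),
       baf = as.numeric(tab$`B Allele Freq`))
}

#' Write a truth annotation as a BED-like table
#'
#' Tab-separated with header, 0-based half-open basepair coordinates:
#' `chrom  start  end  name  copy_number  loh_status  subclone_descriptor
#' n_snps`.  Diploid-heterozygous regions are written too; they are
#' filtered at evaluation time, not at writing time.
#'
#' @param truth a `cna_truth` data.frame or a `cna_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  truth <- as_truth(truth)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("chrom", "start", "end", "name", "copy_number",
                   "loh_status", "subclone_descriptor", "n_snps", sep = "\t"), con)
  writeLines(paste(truth$chrom, truth$start, truth$end, truth$name,
                   truth$copy_number, truth$loh, truth$subclones,
                   truth$n_snps, sep = "\t"), con)
  invisible(path)
}

#' Read a truth annotation written by [write_truth_bed()]
#'
#' @param path file path.
#' @return A `cna_truth` data.frame.
#' @export
read_truth_bed <- function(path) {
  if (!file.exists(path)) stop_("read_truth_bed: file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "name", "copy_number", "loh_status",
            "subclone_descriptor", "n_snps")
  if (!all(need %in% names(tab)))
    stop_("read_truth_bed: missing column(s): %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  out <- data.frame(chrom = tab$chrom, start = as.integer(tab$start),
                    end = as.integer(tab$end), name = tab$name,
                    copy_number = as.integer(tab$copy_number),
                    loh = tab$loh_status, subclones = tab$subclone_descriptor,
                    n_snps = as.integer(tab$n_snps), stringsAsFactors = FALSE)
  class(out) <- c("cna_truth", "data.frame")
  out
}

#' Read caller output as call records
#'
#' Parses a tab-separated file with columns `chrom  start  end  copy_number`
#' and an optional fifth `loh` column (`none`, `somatic`, `germline` or
#' `unspecified`).  Coordinates are 0-based half-open basepairs.  Lines
#' starting with `#` are ignored; an optional header row is detected and
#' skipped.  Overlapping calls are accepted (callers may emit them) but
#' counted in a warning.
#'
#' @param path file path.
#' @return A data.frame of class `cna_calls` with columns `chrom`, `start`,
#'   `end`, `copy_number`, `loh`.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop_("read_calls: file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) &&
      is.na(suppressWarnings(as.numeric(strsplit(lines[1L], "\t")[[1]][2L])))) {
    lines <- lines[-1L]   # header row
    lineno <- lineno[-1L]
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      copy_number = integer(), loh = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) {
    class(empty) <- c("cna_calls", "data.frame")
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L)
      stop_("read_calls: line %d: expected at least 4 tab-separated fields",
            lineno[i])
    se <- suppressWarnings(as.numeric(p[2:3]))
    cn <- suppressWarnings(as.numeric(p[4L]))
    if (anyNA(se) || is.na(cn) || cn != floor(cn) || cn < 0)
      stop_("read_calls: line %d: malformed coordinates or copy number",
            lineno[i])
    if (se[2L] <= se[1L])
      stop_("read_calls: line %d: end <= start", lineno[i])
  }
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, function(p) as.numeric(p[2L]), 0)),
    end = as.integer(vapply(parts, function(p) as.numeric(p[3L]), 0)),
    copy_number = as.integer(vapply(parts, function(p) as.numeric(p[4L]), 0)),
    loh = vapply(parts, function(p)
      if (length(p) >= 5L && nzchar(p[5L])) p[5L] else "unspecified", ""),
    stringsAsFactors = FALSE)
  bad_loh <- !out$loh %in% c("none", "somatic", "germline", "unspecified")
  if (any(bad_loh))
    stop_("read_calls: line %d: unknown loh status '%s'",
          lineno[which(bad_loh)[1L]], out$loh[which(bad_loh)[1L]])
  n_ov <- count_overlaps(out)
  if (n_ov > 0L)
    warning(sprintf("read_calls: %d overlapping call pair(s)", n_ov),
            call. = FALSE)
  class(out) <- c("cna_calls", "data.frame")
  out
}

# number of overlapping call pairs among records sharing a chromosome
count_overlaps <- function(calls) {
  n <- 0L
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    m <- nrow(cc)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      ov <- pmin(cc$end[i], cc$end[(i + 1L):m]) -
            pmax(cc$start[i], cc$start[(i + 1L):m])
      n <- n + sum(ov > 0L)
    }
  }
  n
}

#' Write call records (convenience, mainly for tests and round-trips)
#'
#' @param calls a `cna_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tstart\tend\tcopy_number\tloh", con)
  if (nrow(calls))
    writeLines(paste(calls$chrom, calls$start, calls$end, calls$copy_number,
                     calls$loh %||% "unspecified", sep = "\t"), con)
  invisible(path)
}
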