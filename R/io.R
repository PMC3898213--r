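#' Read a PBM probe table
#'
#' Reads a UniPROBE-style tab-separated table of probes: probe id, the
#' 36bp variable-region sequence, and the measured fluorescence intensity.
#' A header row is detected automatically (third field non-numeric).
#'
#' @param path path to a TSV file with at least 3 columns.
#' @param seq_length required variable-region length (default 36).
#' @param columns integer vector of length 3 giving the positions of the
#'   (id, sequence, intensity) columns, for files in a different order.
#' @return a `data.frame` with columns `probe_id`, `sequence`, `intensity`,
#'   in file order.
#' @export
read_pbm_table <- function(path, seq_length = 36L, columns = c(1L, 2L, 3L)) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(raw) == 0L) {
    warning("empty PBM table: ", path)
    return(data.frame(probe_id = character(0), sequence = character(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  }
  if (ncol(raw) < max(columns))
    stop("PBM table needs at least ", max(columns), " columns: ", path)
  # header detection: intensity field of first row not parseable as number
  if (is.na(suppressWarnings(as.numeric(raw[1L, columns[3L]]))))
    raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) {
    warning("PBM table has a header but no data rows: ", path)
    return(data.frame(probe_id = character(0), sequence = character(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  }
  probes <- data.frame(probe_id = raw[[columns[1L]]],
                       sequence = toupper(raw[[columns[2L]]]),
                       intensity = suppressWarnings(as.numeric(raw[[columns[3L]]])),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in PBM table: ",
         probes$probe_id[anyDuplicated(probes$probe_id)])
  if (any(grepl("[^ACGT]", probes$sequence)))
    stop("probe sequence contains non-ACGT characters")
  if (!is.null(seq_length) && any(nchar(probes$sequence) != seq_length))
    stop("probe sequences must have length ", seq_length)
  if (any(!is.finite(probes$intensity)))
    stop("non-finite probe intensity")
  rownames(probes) <- NULL
  probes
}

#' Read genomic intervals from a BED file
#'
#' BED3+ input; coordinates are kept 0-based half-open (the BED convention,
#' used throughout this package).  The 5th column, when present, is read as
#' a numeric score.
#'
#' @param path path to a BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @export
read_bed_intervals <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = raw[[1L]],
                    start = as.numeric(raw[[2L]]),
                    end = as.numeric(raw[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-numeric BED coordinate in ", path)
  if (any(out$start < 0)) stop("negative BED coordinate in ", path)
  if (any(out$start >= out$end)) stop("BED interval with start >= end in ", path)
  if (ncol(raw) >= 4L) out$name <- raw[[4L]]
  if (ncol(raw) >= 5L) {
    out$score <- suppressWarnings(as.numeric(raw[[5L]]))
    if (any(is.na(out$score))) stop("non-numeric BED score in ", path)
  }
  out
}

#' Coverage track over genomic intervals
#'
#' Builds a queryable per-base coverage track (DNase tag density or
#' conservation score) from bedGraph-style data.  Intervals on a chromosome
#' must not overlap; positions not covered by any interval have value 0
#' (for DNase, absence of tags is read as closed chromatin).
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open).
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end))
    stop("invalid interval coordinates in coverage track")
  if (any(intervals$value < 0))
    stop("coverage values must be non-negative")
  by_chrom <- split(intervals[c("start", "end", "value")], intervals$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$end[-nrow(d)] > d$start[-1L]))
      stop("overlapping intervals on the same chromosome in coverage track")
    d
  })
  structure(list(data = by_chrom), class = "coverage_track")
}

#' Read a bedGraph file into a coverage track
#'
#' @param path path to a 4-column bedGraph file (chrom, start, end, value).
#' @param conservation if `TRUE`, additionally require values in `[0,1]`
#'   (phastCons-style scores).
#' @return a `coverage_track`.
#' @export
read_coverage_track <- function(path, conservation = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 4L) stop("bedGraph file needs 4 columns: ", path)
  d <- data.frame(chrom = raw[[1L]], start = as.numeric(raw[[2L]]),
                  end = as.numeric(raw[[3L]]), value = as.numeric(raw[[4L]]),
                  stringsAsFactors = FALSE)
  if (any(is.na(d$start) | is.na(d$end) | is.na(d$value)))
    stop("non-numeric field in bedGraph file ", path)
  if (conservation && any(d$value < 0 | d$value > 1))
    stop("conservation scores must lie in [0, 1]")
  coverage_track(d)
}

#' Mean track value over a window
#'
#' Length-weighted mean of the track over `[start, end)`; uncovered bases
#' contribute 0.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return a single non-negative number.
#' @export
track_mean <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"), end > start)
  d <- track$data[[chrom]]
  if (is.null(d)) return(0)
  w <- pmax(0, pmin(d$end, end) - pmax(d$start, start))
  sum(w * d$value) / (end - start)
}

#' Write scored binding-site predictions as BED
#'
#' Writes sites as BED6+4: chrom, start, end, name, score (the posterior),
#' strand (`.`), followed by the in-vitro binding probability `B`, the
#' open-chromatin probability, the occupancy `X`, and the posterior
#' probability of binding.  Numeric columns carry 6 significant digits;
#' rows are sorted by (chrom, start).
#'
#' @param sites `data.frame` with columns `chrom`, `start`, `end`, `B`,
#'   `p_open`, `X`, `posterior` (optional `name`).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_predictions <- function(sites, path) {
  need <- c("chrom", "start", "end", "B", "p_open", "X", "posterior")
  stopifnot(all(need %in% names(sites)))
  num <- sites[c("B", "p_open", "X", "posterior")]
  if (nrow(sites) > 0L && any(!is.finite(as.matrix(num))))
    stop("non-finite score in predictions")
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ord <- order(sites$chrom, sites$start)
  sites <- sites[ord, , drop = FALSE]
  name <- if ("name" %in% names(sites)) sites$name else
    sprintf("site_%d", seq_len(nrow(sites)))
  out <- data.frame(sites$chrom, sites$start, sites$end, name,
                    signif(sites$posterior, 6), ".",
                    signif(sites$B, 6), signif(sites$p_open, 6),
                    signif(sites$X, 6), signif(sites$posterior, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
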