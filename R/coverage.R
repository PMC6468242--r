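#' Construct a coverage track from binned read counts
#'
#' A coverage track stores per-base read counts for one sequencing sample as
#' run-length-encoded vectors (one per chromosome) together with the
#' sample's total mapped-read count, which is the denominator for RPM
#' (reads per million mapped reads) normalisation. Input intervals follow
#' the bedGraph convention: 0-based half-open with a `count` applied to
#' every base of the interval.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `count`
#'   (non-negative read counts).
#' @param total_reads Total mapped reads for the sample (positive).
#' @param sample_id,chip_factor,replicate_id Optional sample metadata;
#'   `chip_factor` is the immunoprecipitated factor, or `"input"` for a
#'   total-chromatin control.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(intervals, total_reads, sample_id = NA_character_,
                           chip_factor = NA_character_, replicate_id = NA_character_) {
  validate_intervals(intervals, "intervals")
  assert_scalar_number(total_reads, "total_reads", positive = TRUE)
  if (nrow(intervals) > 0 && (!is.numeric(intervals$count) || any(intervals$count < 0))) {
    abort("`intervals$count` must be non-negative numbers.")
  }
  cov <- if (nrow(intervals) == 0) {
    IRanges::RleList()
  } else {
    gr <- gi_to_gr(intervals)
    GenomicRanges::coverage(gr, weight = intervals$count)
  }
  new_coverage_track(cov, total_reads, sample_id, chip_factor, replicate_id)
}

new_coverage_track <- function(cov, total_reads, sample_id = NA_character_,
                               chip_factor = NA_character_, replicate_id = NA_character_) {
  structure(
    list(
      cov = cov,
      total_reads = total_reads,
      sample_id = sample_id,
      chip_factor = chip_factor,
      replicate_id = replicate_id
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> sample=%s factor=%s replicate=%s\n  %d chromosome(s), %s total mapped reads\n",
    x$sample_id, x$chip_factor, x$replicate_id,
    length(x$cov), format(x$total_reads, big.mark = ",")
  ))
  invisible(x)
}

#' Read a bedGraph coverage file into a coverage track
#'
#' Reads 4-column bedGraph text (`chrom`, `start`, `end`, `count`); `track`
#' and comment lines are skipped. The total mapped-read count is not part of
#' the bedGraph format and must be supplied alongside (the pipeline carries
#' it in a sidecar table).
#'
#' @inheritParams coverage_track
#' @param path Path to a bedGraph file.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, total_reads, sample_id = NA_character_,
                          chip_factor = NA_character_, replicate_id = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), count = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  x <- x[!startsWith(x$chrom, "track"), ]
  coverage_track(x, total_reads, sample_id, chip_factor, replicate_id)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param drop_zero Omit zero-count runs (default `TRUE`, the usual
#'   bedGraph convention).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- purrr::map2_dfr(as.list(track$cov), names(track$cov), function(r, chr) {
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    ends <- cumsum(len)
    tibble(chrom = chr, start = ends - len, end = ends, count = val)
  })
  if (drop_zero) rows <- rows[rows$count != 0, ]
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

## per-base counts over a 0-based half-open window, zero-padded outside the
## covered extent; errors on unknown chromosome
window_counts <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$cov)) {
    abort(sprintf("Chromosome not present in coverage track: %s", chrom))
  }
  r <- track$cov[[chrom]]
  n <- end - start
  out <- numeric(n)
  lo <- max(start, 0L)
  hi <- min(end, length(r))
  if (hi > lo) {
    out[(lo - start + 1):(hi - start)] <- as.numeric(S4Vectors::window(r, lo + 1L, hi))
  }
  out
}

## fast window sum without materialising per-base vectors
window_sum <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$cov)) {
    abort(sprintf("Chromosome not present in coverage track: %s", chrom))
  }
  r <- track$cov[[chrom]]
  lo <- max(start, 0L)
  hi <- min(end, length(r))
  if (hi <= lo) {
    return(0)
  }
  sum(as.numeric(S4Vectors::window(r, lo + 1L, hi)))
}

#' RPM signal in genomic windows
#'
#' Sums the read counts of a coverage track over each query interval and
#' normalises by the track's total mapped reads:
#' `sum(counts) * 1e6 / total_reads`.
#'
#' @param windows Tibble of query intervals (`chrom`, `start`, `end`).
#' @param track A `coverage_track`.
#' @return Numeric vector of RPM values, one per window.
#' @export
rpm_in_window <- function(windows, track) {
  validate_intervals(windows, "windows")
  stopifnot(inherits(track, "coverage_track"))
  if (nrow(windows) == 0) {
    return(numeric())
  }
  sums <- vapply(
    seq_len(nrow(windows)),
    function(i) window_sum(track, windows$chrom[i], windows$start[i], windows$end[i]),
    numeric(1)
  )
  sums * 1e6 / track$total_reads
}
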