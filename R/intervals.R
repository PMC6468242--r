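#' Read peak calls in narrowPeak / BED format
#'
#' Reads a MACS2 narrowPeak (BED6+4) or plain BED3+ file into a tibble of
#' genomic intervals. Coordinates follow the BED convention: 0-based,
#' half-open `[start, end)`. Columns beyond the third are kept as `name`
#' (column 4) and `score` (column 5) where present. Identical duplicate
#' intervals are dropped, and peaks are returned sorted by position.
#'
#' @param path Path to a tab-separated narrowPeak/BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`.
#' @seealso [write_narrowpeak()], [merge_intervals()]
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr2L\t100\t200\tp1\t50", f)
#' read_narrowpeak(f)
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double()
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3)) {
    bad <- idx[which(nfield < 3)[1]]
    abort(sprintf("Malformed narrowPeak/BED line %d: fewer than 3 tab-separated columns.", bad))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad_coord <- is.na(start) | is.na(end) | !is_whole2(start) | !is_whole2(end)
  if (any(bad_coord)) {
    abort(sprintf("Malformed narrowPeak/BED line %d: non-integer coordinates.", idx[which(bad_coord)[1]]))
  }
  if (any(end <= start) || any(start < 0)) {
    bad <- idx[which(end <= start | start < 0)[1]]
    abort(sprintf("Malformed narrowPeak/BED line %d: requires 0 <= start < end.", bad))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(start),
    end = as.integer(end),
    name = ifelse(nfield >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_),
    score = suppressWarnings(as.numeric(
      ifelse(nfield >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA_character_)
    ))
  )
  out <- dplyr::distinct(out, chrom, start, end, .keep_all = TRUE)
  sort_intervals(out)
}

is_whole2 <- function(x) !is.na(x) & x == floor(x)

#' Write intervals to a narrowPeak-style BED file
#'
#' Inverse of [read_narrowpeak()]: writes `chrom`, `start`, `end` and, when
#' present, `name` and `score` columns as tab-separated text.
#'
#' @param peaks Tibble of intervals (`chrom`, `start`, `end`, optional
#'   `name`, `score`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks, "peaks")
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(peaks)) cols <- c(cols, "name")
  if ("score" %in% names(peaks) && "name" %in% names(peaks)) cols <- c(cols, "score")
  out <- peaks[, cols, drop = FALSE]
  if ("name" %in% names(out)) out$name[is.na(out$name)] <- "."
  if ("score" %in% names(out)) out$score[is.na(out$score)] <- 0
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge overlapping and bookended genomic intervals
#'
#' Reduces a set of intervals to the minimal sorted, pairwise-disjoint set
#' covering exactly the same bases. Overlapping intervals and bookended
#' intervals (one ending where the next starts) are merged. This is the
#' "combine and reduce" step used to build a reference peak set from the
#' union of peak calls.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble with `chrom`, `start`, `end`, sorted and disjoint.
#' @examples
#' merge_intervals(tibble::tibble(
#'   chrom = "chr2L", start = c(0L, 5L), end = c(10L, 15L)
#' ))
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(gi_to_gr(intervals))
  sort_intervals(gr_to_gi(gr))
}

#' Fraction of intervals in one set overlapping another
#'
#' Computes the proportion of intervals in `a` that overlap, by at least one
#' base, any interval in `b`. Used e.g. to ask what fraction of Ada2b peaks
#' coincide with Spt3 peaks; `1 - overlap_fraction(a, b)` gives the
#' non-overlap fraction.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`); `a` must be
#'   non-empty.
#' @return A single number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  if (nrow(a) == 0) {
    abort("`a` is empty: overlap fraction is undefined.")
  }
  if (nrow(b) == 0) {
    return(0)
  }
  ## sets on entirely different chromosomes are a valid query; silence the
  ## GRanges no-common-seqlevels warning for that case
  hits <- suppressWarnings(GenomicRanges::countOverlaps(gi_to_gr(a), gi_to_gr(b)))
  mean(hits > 0)
}
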