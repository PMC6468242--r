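## internal helpers shared across modules

## intervals are tibbles in BED convention: 0-based half-open [start, end)
validate_intervals <- function(x, arg = "intervals", require_cols = c("chrom", "start", "end")) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of genomic intervals.", arg))
  }
  missing_cols <- setdiff(require_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(invisible(x))
  }
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort(sprintf("`%s` has empty chromosome names.", arg))
  }
  if (any(x$start < 0)) {
    abort(sprintf("`%s` has negative start coordinates.", arg))
  }
  if (any(x$end <= x$start)) {
    abort(sprintf("`%s` has intervals with end <= start (half-open convention requires end > start).", arg))
  }
  invisible(x)
}

## BED half-open tibble -> GRanges (1-based closed)
gi_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

## GRanges -> BED half-open tibble
gr_to_gi <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

sort_intervals <- function(x) {
  dplyr::arrange(x, chrom, start, end)
}

## integer-valued numeric check (coordinates, counts)
is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & x == floor(x)
}

assert_scalar_number <- function(x, arg, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", arg))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", arg))
  }
  invisible(x)
}
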