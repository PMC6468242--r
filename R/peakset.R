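#' Reproducibility-filtered peaks for one factor
#'
#' Keeps the peaks (from any replicate) that overlap, by at least one base,
#' peaks from at least `min_support` distinct replicates, then merges the
#' survivors. A peak always supports itself, so its own replicate counts
#' towards the support. This implements replicate-reproducibility filters of
#' the form "present in at least two of three replicates".
#'
#' @param peaks Tibble of peak calls pooled over the replicates of one
#'   factor, with columns `chrom`, `start`, `end` and `replicate` (replicate
#'   label).
#' @param min_support Minimum number of distinct supporting replicates
#'   (between 1 and the number of replicates present).
#' @return Merged tibble (`chrom`, `start`, `end`) of reproducible regions.
#' @examples
#' pk <- tibble::tibble(
#'   chrom = "chr2L",
#'   start = c(100L, 110L, 500L),
#'   end = c(200L, 210L, 600L),
#'   replicate = c("r1", "r2", "r1")
#' )
#' reproducible_peaks(pk, min_support = 2)
#' @export
reproducible_peaks <- function(peaks, min_support) {
  validate_intervals(peaks, "peaks")
  if (!"replicate" %in% names(peaks)) {
    abort("`peaks` must have a `replicate` column.")
  }
  assert_scalar_number(min_support, "min_support", positive = TRUE)
  if (min_support != floor(min_support)) {
    abort("`min_support` must be a whole number.")
  }
  n_rep <- dplyr::n_distinct(peaks$replicate)
  if (nrow(peaks) == 0) {
    if (min_support > 1) {
      abort("`min_support` exceeds the number of replicates present.")
    }
    return(merge_intervals(peaks))
  }
  if (min_support > n_rep) {
    abort(sprintf(
      "`min_support` (%d) exceeds the number of replicates present (%d).",
      as.integer(min_support), n_rep
    ))
  }
  peaks <- dplyr::distinct(peaks, chrom, start, end, replicate)
  gr <- gi_to_gr(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  rep_of <- peaks$replicate
  support <- tapply(
    rep_of[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    function(r) length(unique(r))
  )
  n_support <- integer(nrow(peaks))
  n_support[as.integer(names(support))] <- as.integer(support)
  merge_intervals(peaks[n_support >= min_support, c("chrom", "start", "end")])
}

#' Classify reference loci by factor support
#'
#' Applies the SAGA/ADA classification rule to per-factor support flags:
#' a locus supported by the HAT-module factor (default `Ada2b`) but by
#' neither of the SAGA-specific factors (defaults `Spt3`, `Sgf11`) is an
#' `ada2b_only` locus; a locus supported by all three factors is a
#' `canonical` SAGA site; every other support pattern is `other`.
#'
#' @param support A data frame with one logical column per factor (rows are
#'   loci), or a single named logical vector.
#' @param ada_factor Name of the factor whose exclusive binding defines the
#'   `ada2b_only` class.
#' @param saga_factors Names of the factors that must also be bound at
#'   canonical sites and absent at `ada2b_only` sites.
#' @return Character vector of classes (`"canonical"`, `"ada2b_only"`,
#'   `"other"`), one per row of `support`.
#' @examples
#' classify_locus(c(Ada2b = TRUE, Spt3 = FALSE, Sgf11 = FALSE))
#' @export
classify_locus <- function(support, ada_factor = "Ada2b",
                           saga_factors = c("Spt3", "Sgf11")) {
  if (is.logical(support) && !is.data.frame(support)) {
    support <- as_tibble(as.list(support))
  }
  needed <- c(ada_factor, saga_factors)
  missing_f <- setdiff(needed, names(support))
  if (length(missing_f) > 0) {
    abort(sprintf("`support` is missing factor(s): %s.", paste(missing_f, collapse = ", ")))
  }
  ada <- support[[ada_factor]]
  others <- as.matrix(support[, saga_factors, drop = FALSE])
  any_other <- rowSums(others) > 0
  all_other <- rowSums(others) == length(saga_factors)
  dplyr::case_when(
    ada & all_other ~ "canonical",
    ada & !any_other ~ "ada2b_only",
    .default = "other"
  )
}

#' Build and classify the reference peak set
#'
#' Merges the reproducible peaks of all factors into a single non-overlapping
#' reference set, flags each reference locus with the factors whose peaks it
#' overlaps (by at least one base), and assigns the locus class with
#' [classify_locus()]. A configured factor with no peak set contributes
#' `FALSE` support everywhere.
#'
#' @param peak_sets Named list of interval tibbles, one per factor
#'   (typically the output of [reproducible_peaks()]).
#' @param ada_factor,saga_factors Classification configuration passed to
#'   [classify_locus()].
#' @return Tibble with `chrom`, `start`, `end`, one logical support column
#'   per factor, and `locus_class`.
#' @export
build_reference_set <- function(peak_sets, ada_factor = "Ada2b",
                                saga_factors = c("Spt3", "Sgf11")) {
  if (!is.list(peak_sets) || is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    abort("`peak_sets` must be a named list of interval tibbles (one per factor).")
  }
  purrr::walk2(peak_sets, names(peak_sets), function(x, nm) validate_intervals(x, nm))
  pooled <- dplyr::bind_rows(lapply(peak_sets, function(x) x[, c("chrom", "start", "end")]))
  reference <- merge_intervals(pooled)
  factors <- union(names(peak_sets), c(ada_factor, saga_factors))
  if (nrow(reference) == 0) {
    out <- reference
    for (f in factors) out[[f]] <- logical()
    out$locus_class <- character()
    return(out)
  }
  ref_gr <- gi_to_gr(reference)
  for (f in factors) {
    pk <- peak_sets[[f]]
    reference[[f]] <- if (is.null(pk) || nrow(pk) == 0) {
      rep(FALSE, nrow(reference))
    } else {
      GenomicRanges::countOverlaps(ref_gr, gi_to_gr(pk)) > 0
    }
  }
  reference$locus_class <- classify_locus(
    reference[, factors, drop = FALSE],
    ada_factor = ada_factor, saga_factors = saga_factors
  )
  reference
}
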