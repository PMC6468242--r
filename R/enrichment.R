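#' Log2 ChIP/input enrichment at loci
#'
#' Computes, for each locus, the log2 ratio of the ChIP RPM signal over the
#' total-chromatin (input) RPM signal. A pseudocount (in RPM units) is added
#' to both numerator and denominator so loci with zero signal are defined.
#'
#' @param loci Tibble of reference loci (`chrom`, `start`, `end`).
#' @param chip,input `coverage_track` objects for the ChIP sample and the
#'   total-chromatin control.
#' @param pseudocount RPM pseudocount added to both signals (default 0.5).
#' @return Numeric vector of log2 ratios, one per locus.
#' @export
locus_log2_enrichment <- function(loci, chip, input, pseudocount = 0.5) {
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  chip_rpm <- rpm_in_window(loci, chip)
  input_rpm <- rpm_in_window(loci, input)
  log2((chip_rpm + pseudocount) / (input_rpm + pseudocount))
}

#' Average enrichment values across replicates
#'
#' Arithmetic mean of per-replicate log2 enrichment values.
#'
#' @param values Numeric vector (one value per replicate); must be
#'   non-empty.
#' @return The mean.
#' @export
average_replicates <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    abort("`values` must be a non-empty numeric vector.")
  }
  mean(values)
}

#' Population z-scores
#'
#' Standardises a vector by subtracting the population mean and dividing by
#' the population standard deviation (the divide-by-N form, not the sample
#' N-1 form). The output always has mean 0 and population sd 1.
#'
#' @param values Numeric vector with at least two values and non-zero
#'   spread.
#' @return Numeric vector of z-scores.
#' @export
zscores <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values)) {
    abort("`values` must be a numeric vector with at least 2 non-missing values.")
  }
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    abort("Degenerate population: all values are equal, standard deviation is zero.")
  }
  (values - mu) / sigma
}

#' Per-locus enrichment and z-score table for several factors
#'
#' Convenience wrapper that, for each factor, computes the per-replicate
#' log2 ChIP/input enrichment at every reference locus, averages the
#' replicates, and converts the averaged enrichments to population z-scores
#' over all reference loci of that factor.
#'
#' @param reference Tibble of reference loci; any extra columns (support
#'   flags, `locus_class`) are carried through.
#' @param tracks List of `coverage_track` objects for the ChIP samples;
#'   their `chip_factor`/`replicate_id` fields define the grouping.
#' @param input `coverage_track` for the total-chromatin control.
#' @param pseudocount RPM pseudocount, see [locus_log2_enrichment()].
#' @return A long tibble: the reference columns plus `factor_name`,
#'   `mean_log2` and `z`.
#' @export
enrichment_table <- function(reference, tracks, input, pseudocount = 0.5) {
  validate_intervals(reference, "reference")
  if (nrow(reference) < 2) {
    abort("`reference` must contain at least 2 loci for z-scoring.")
  }
  factors <- unique(vapply(tracks, function(t) t$chip_factor, character(1)))
  purrr::map_dfr(factors, function(f) {
    reps <- tracks[vapply(tracks, function(t) identical(t$chip_factor, f), logical(1))]
    per_rep <- vapply(
      reps,
      function(t) locus_log2_enrichment(reference, t, input, pseudocount),
      numeric(nrow(reference))
    )
    mean_log2 <- rowMeans(per_rep)
    dplyr::mutate(
      reference,
      factor_name = f,
      mean_log2 = mean_log2,
      z = zscores(mean_log2)
    )
  })
}
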