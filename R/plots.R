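#' Plot a column calibration
#'
#' Markers and the fitted elution-to-Stokes-radius model.
#'
#' @param object A `column_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.column_calibration <- function(object, ...) {
  mk <- object$markers
  rng <- range(mk$elution_volume)
  grid <- tibble(elution_volume = seq(rng[1], rng[2], length.out = 100))
  grid$stokes_radius <- as.numeric(suppressWarnings(stokes_radius(object, grid$elution_volume)))
  ggplot2::ggplot(mk, ggplot2::aes(x = elution_volume, y = stokes_radius)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = name), hjust = -0.1, vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = "Elution volume (ml)", y = "Stokes radius (nm)",
      title = sprintf("Gel-filtration calibration (%s fit)", object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Z-score distributions by locus class and factor
#'
#' Boxplots of the per-factor enrichment z-scores, split by reference locus
#' class — the canonical-vs-ada2b-only comparison showing which factors are
#' enriched at which class of site.
#'
#' @param enrichment_tbl Output of [enrichment_table()] (needs
#'   `locus_class`, `factor_name`, `z`).
#' @param classes Locus classes to show (default canonical and ada2b-only).
#' @return A ggplot object.
#' @export
plot_zscore_distributions <- function(enrichment_tbl,
                                      classes = c("canonical", "ada2b_only")) {
  x <- dplyr::filter(enrichment_tbl, locus_class %in% classes)
  ggplot2::ggplot(x, ggplot2::aes(x = factor_name, y = z)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linetype = 2) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~locus_class) +
    ggplot2::labs(x = NULL, y = "Enrichment z-score") +
    ggplot2::theme_minimal()
}

#' dNSAF abundance heatmap
#'
#' Tile heatmap of a sorted abundance matrix (see [abundance_matrix()]),
#' proteins in rows (sorted order preserved), runs in columns.
#'
#' @param matrix_tbl A `dnsaf_matrix` tibble.
#' @param top Show only the `top` most abundant proteins (default all).
#' @return A ggplot object.
#' @export
plot_dnsaf_heatmap <- function(matrix_tbl, top = Inf) {
  x <- utils::head(matrix_tbl, n = top)
  long <- tidyr::pivot_longer(x, cols = -protein_id,
                              names_to = "run_id", values_to = "dnsaf")
  long$protein_id <- factor(long$protein_id, levels = rev(x$protein_id))
  long$run_id <- factor(long$run_id, levels = setdiff(names(x), "protein_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = run_id, y = protein_id, fill = dnsaf)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "yellow") +
    ggplot2::labs(x = NULL, y = NULL, fill = "dNSAF") +
    ggplot2::theme_minimal()
}

#' Average TSS-centred signal profile
#'
#' Column means of a TSS intensity matrix: the average RPM signal as a
#' function of distance from the TSS (positive = downstream).
#'
#' @param mat An `intensity_matrix` from [tss_intensity_matrix()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  prof <- tibble(
    position = as.integer(colnames(mat)),
    signal = colMeans(unclass(mat))
  )
  ggplot2::ggplot(prof, ggplot2::aes(x = position, y = signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60", linetype = 2) +
    ggplot2::labs(x = "Position relative to TSS (bp)", y = "Mean signal (RPM)") +
    ggplot2::theme_minimal()
}
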