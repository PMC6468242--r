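#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a column calibration
#'
#' One row per fitted coefficient of the elution-to-Stokes-radius model.
#'
#' @param x A `column_calibration`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.column_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", if (x$method == "porath") "sqrt_neg_log_kav" else "elution_volume"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"])
  )
}

#' Summarise a column calibration fit
#'
#' @param x A `column_calibration`.
#' @param ... Unused.
#' @return One-row tibble with the method, marker count, R squared and
#'   residual standard deviation (nm).
#' @export
glance.column_calibration <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    method = x$method,
    n_markers = nrow(x$markers),
    r.squared = sm$r.squared,
    sigma = sm$sigma
  )
}

#' Tidy a mass estimate
#'
#' @param x A `mass_estimate` from [svedberg_mass()].
#' @param ... Unused.
#' @return One-row tibble with the mass (kDa), its uncertainty and the
#'   inputs used.
#' @export
tidy.mass_estimate <- function(x, ...) {
  tibble(
    mass_kda = x$mass, uncertainty_kda = x$uncertainty,
    rs_nm = x$rs, s_svedberg = x$s,
    vbar = x$vbar, rho = x$rho, eta = x$eta
  )
}
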