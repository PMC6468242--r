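#' Size-exclusion partition coefficient
#'
#' Kav = (Ve - V0) / (Vt - V0): the fraction of the accessible column
#' volume at which a species elutes, 0 at the void volume and 1 at the
#' total column volume.
#'
#' @param ve Elution volume (ml).
#' @param v0 Void volume (ml).
#' @param vt Total column volume (ml).
#' @return Partition coefficient(s) in `(0, 1]`.
#' @export
kav <- function(ve, v0, vt) {
  assert_scalar_number(v0, "v0", positive = TRUE)
  assert_scalar_number(vt, "vt", positive = TRUE)
  if (vt <= v0) {
    abort("`vt` must exceed `v0`.")
  }
  if (any(ve <= v0)) {
    abort("Elution volume at or before the void volume: Kav is undefined.")
  }
  if (any(ve > vt)) {
    abort("Elution volume exceeds the total column volume.")
  }
  (ve - v0) / (vt - v0)
}

#' Convert a collected fraction number to an elution volume
#'
#' With fractions of `fraction_ml` each collected from the start of the
#' run, fraction `k` spans `((k-1) * fraction_ml, k * fraction_ml]`; its
#' midpoint `(k - 0.5) * fraction_ml` is used as the peak elution volume.
#'
#' @param fraction Fraction number(s).
#' @param fraction_ml Fraction size in ml (default 0.5, i.e. 500 ul).
#' @return Elution volume(s) in ml.
#' @export
fraction_to_volume <- function(fraction, fraction_ml = 0.5) {
  assert_scalar_number(fraction_ml, "fraction_ml", positive = TRUE)
  (fraction - 0.5) * fraction_ml
}

#' Calibrate a gel-filtration column from marker proteins
#'
#' Fits a mapping from elution volume to Stokes radius using globular
#' marker proteins of known radius. The default method is a least-squares
#' line of Rs versus elution volume; method `"porath"` fits Rs against
#' `sqrt(-log(Kav))` and requires the void and total column volumes.
#'
#' @param markers Tibble with columns `name`, `stokes_radius` (nm) and
#'   `elution_volume` (ml); at least two markers with distinct elution
#'   volumes.
#' @param v0,vt Void and total column volumes (ml); required for
#'   `method = "porath"`.
#' @param method `"linear"` (default) or `"porath"`.
#' @return An object of class `column_calibration` holding the markers, the
#'   fitted model and its residuals. Supports [stokes_radius()],
#'   `autoplot()`, `tidy()` and `glance()`.
#' @export
calibrate_stokes <- function(markers, v0 = NULL, vt = NULL,
                             method = c("linear", "porath")) {
  method <- match.arg(method)
  needed <- c("name", "stokes_radius", "elution_volume")
  if (!is.data.frame(markers) || !all(needed %in% names(markers))) {
    abort("`markers` must have columns name, stokes_radius, elution_volume.")
  }
  if (nrow(markers) < 2 || dplyr::n_distinct(markers$elution_volume) < 2) {
    abort("Calibration needs at least 2 markers with distinct elution volumes.")
  }
  if (any(markers$stokes_radius <= 0)) {
    abort("Marker Stokes radii must be positive.")
  }
  ord <- order(markers$elution_volume)
  if (is.unsorted(-markers$stokes_radius[ord], strictly = FALSE)) {
    warn("Marker table is not monotone (larger Rs should elute earlier); calibration may be unreliable.")
  }
  markers <- as_tibble(markers)
  if (method == "porath") {
    if (is.null(v0) || is.null(vt)) {
      abort("Method 'porath' requires `v0` and `vt`.")
    }
    markers$.x <- sqrt(-log(kav(markers$elution_volume, v0, vt)))
  } else {
    markers$.x <- markers$elution_volume
  }
  fit <- lm(stokes_radius ~ .x, data = markers)
  structure(
    list(
      markers = markers[, needed],
      v0 = v0, vt = vt, method = method, fit = fit,
      residuals = unname(stats::residuals(fit))
    ),
    class = "column_calibration"
  )
}

#' @export
print.column_calibration <- function(x, ...) {
  cat(sprintf(
    "<column_calibration> method=%s, %d markers\n  Rs = %.4g %+.4g * %s\n  residual range [%.3g, %.3g] nm\n",
    x$method, nrow(x$markers),
    coef(x$fit)[1], coef(x$fit)[2],
    if (x$method == "porath") "sqrt(-log Kav)" else "Ve",
    min(x$residuals), max(x$residuals)
  ))
  invisible(x)
}

#' Stokes radius from an elution volume
#'
#' Evaluates a fitted column calibration at the observed elution volume.
#' Volumes outside the marker range are extrapolations and are flagged with
#' a warning and an `extrapolated` attribute.
#'
#' @param calibration A `column_calibration` from [calibrate_stokes()].
#' @param ve Elution volume(s) in ml.
#' @return Estimated Stokes radius (nm) with attribute `extrapolated`.
#' @export
stokes_radius <- function(calibration, ve) {
  stopifnot(inherits(calibration, "column_calibration"))
  x <- if (calibration$method == "porath") {
    sqrt(-log(kav(ve, calibration$v0, calibration$vt)))
  } else {
    ve
  }
  extrap <- ve < min(calibration$markers$elution_volume) |
    ve > max(calibration$markers$elution_volume)
  if (any(extrap)) {
    warn("Elution volume outside the calibrated marker range; Stokes radius is an extrapolation.")
  }
  rs <- unname(predict(calibration$fit, newdata = data.frame(.x = x)))
  attr(rs, "extrapolated") <- extrap
  rs
}

#' Sedimentation coefficient from a gradient position
#'
#' Fits a least-squares line of sedimentation coefficient versus fraction
#' number through gradient standards and evaluates it at the sample's peak
#' fraction.
#'
#' @param markers Tibble with columns `fraction` and `s` (Svedberg units);
#'   at least two standards.
#' @param peak_fraction Fraction number at which the sample peaks.
#' @return Estimated sedimentation coefficient(s) in Svedberg units.
#' @export
sedimentation_from_gradient <- function(markers, peak_fraction) {
  if (!is.data.frame(markers) || !all(c("fraction", "s") %in% names(markers))) {
    abort("`markers` must have columns `fraction` and `s`.")
  }
  if (nrow(markers) < 2 || dplyr::n_distinct(markers$fraction) < 2) {
    abort("Gradient calibration needs at least 2 standards with distinct fractions.")
  }
  fit <- lm(s ~ fraction, data = markers)
  unname(predict(fit, newdata = data.frame(fraction = peak_fraction)))
}

#' Native mass from hydrodynamic properties (Svedberg equation)
#'
#' Combines a Stokes radius (gel filtration) and a sedimentation
#' coefficient (density-gradient centrifugation) into a native molecular
#' mass, independent of molecular shape:
#' `M = 6 * pi * eta * N_A * Rs * s / (1 - vbar * rho)`,
#' with Rs in cm, s in seconds, and the result reported in kDa. Defaults
#' assume water at 20 C (viscosity 0.01002 poise, density 0.9982 g/cm^3)
#' and a typical protein partial specific volume of 0.73 mL/g.
#'
#' When input uncertainties are supplied, a first-order (delta-method)
#' uncertainty is propagated to the mass.
#'
#' @param rs Stokes radius in nm.
#' @param s Sedimentation coefficient in Svedberg units (1 S = 1e-13 s).
#' @param vbar Partial specific volume, mL/g (default 0.73).
#' @param rho Solvent density, g/cm^3 (default 0.9982).
#' @param eta Solvent viscosity, poise (default 0.01002).
#' @param rs_sd,s_sd,vbar_sd Optional standard uncertainties of `rs`, `s`
#'   and `vbar`.
#' @return An object of class `mass_estimate` with fields `mass` (kDa) and
#'   `uncertainty` (kDa, `NA` when no input uncertainties are given).
#' @examples
#' svedberg_mass(rs = 7.8, s = 7.3)
#' @export
svedberg_mass <- function(rs, s, vbar = 0.73, rho = 0.9982, eta = 0.01002,
                          rs_sd = NULL, s_sd = NULL, vbar_sd = NULL) {
  assert_scalar_number(rs, "rs", positive = TRUE)
  assert_scalar_number(s, "s", positive = TRUE)
  assert_scalar_number(vbar, "vbar", positive = TRUE)
  assert_scalar_number(rho, "rho", positive = TRUE)
  assert_scalar_number(eta, "eta", positive = TRUE)
  buoyancy <- 1 - vbar * rho
  if (buoyancy <= 0) {
    abort("vbar * rho >= 1: the particle would float; Svedberg mass is undefined.")
  }
  avogadro <- 6.02214e23
  rs_cm <- rs * 1e-7
  s_sec <- s * 1e-13
  mass_da <- 6 * pi * eta * avogadro * rs_cm * s_sec / buoyancy
  mass_kda <- mass_da / 1000
  uncertainty <- NA_real_
  if (!is.null(rs_sd) || !is.null(s_sd) || !is.null(vbar_sd)) {
    rel2 <- 0
    if (!is.null(rs_sd)) rel2 <- rel2 + (rs_sd / rs)^2
    if (!is.null(s_sd)) rel2 <- rel2 + (s_sd / s)^2
    if (!is.null(vbar_sd)) rel2 <- rel2 + (vbar_sd * rho / buoyancy)^2
    uncertainty <- mass_kda * sqrt(rel2)
  }
  structure(
    list(
      mass = mass_kda, uncertainty = uncertainty,
      rs = rs, s = s, vbar = vbar, rho = rho, eta = eta
    ),
    class = "mass_estimate"
  )
}

#' @export
print.mass_estimate <- function(x, ...) {
  if (is.na(x$uncertainty)) {
    cat(sprintf("Native mass estimate: %.1f kDa\n", x$mass))
  } else {
    cat(sprintf("Native mass estimate: %.1f +/- %.1f kDa\n", x$mass, x$uncertainty))
  }
  cat(sprintf(
    "  (Rs = %.3g nm, s = %.3g S, vbar = %.3g mL/g, rho = %.4g g/cm^3, eta = %.4g poise)\n",
    x$rs, x$s, x$vbar, x$rho, x$eta
  ))
  invisible(x)
}
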