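#' Sampled spectral function
#'
#' A `spectrum` holds a spectral power distribution (radiance, arbitrary
#' linear power units) or a spectral reflectance, sampled on a strictly
#' increasing, uniformly spaced wavelength grid. The package default grid is
#' 390--780 nm at 1 nm, matching the working range of the colorimetric
#' pipeline.
#'
#' @param wavelengths_nm numeric vector, strictly increasing, uniform step.
#' @param values numeric vector the same length; power values must be
#'   nonnegative, reflectance values must lie in `[0, 1.05]` (a small
#'   tolerance over 1 accommodates glossy printed samples).
#' @param kind `"power"` or `"reflectance"`.
#' @return An object of class `spectrum` with fields `wavelengths_nm`,
#'   `values`, `kind`.
#' @examples
#' flat <- spectrum(390:780, rep(1, 391), "power")
#' @export
spectrum <- function(wavelengths_nm, values, kind = c("power", "reflectance")) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) < 2L) {
    stop("a spectrum needs at least two samples", call. = FALSE)
  }
  if (length(values) != length(wavelengths_nm)) {
    stop("wavelengths and values differ in length", call. = FALSE)
  }
  steps <- diff(wavelengths_nm)
  if (any(steps <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (max(steps) - min(steps) > 1e-9 * mean(steps)) {
    stop("wavelength grid must be uniformly spaced", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("spectral values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop(sprintf("%s values must be nonnegative", kind), call. = FALSE)
  }
  if (kind == "reflectance" && any(values > 1.05)) {
    stop("reflectance values must lie in [0, 1.05]", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values, kind = kind),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum: %s, %d samples, %g-%g nm at %g nm>\n",
    x$kind, length(x$values),
    min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$wavelengths_nm[2] - x$wavelengths_nm[1]
  ))
  invisible(x)
}

#' Default wavelength grid (390--780 nm at 1 nm)
#' @return Integer-valued numeric vector of wavelengths in nm.
#' @export
default_grid <- function() {
  seq(390, 780, by = 1)
}

#' Equal-energy spectrum
#'
#' A flat power spectrum, the normalization anchor of the MacLeod-Boynton
#' diagram used throughout the package.
#'
#' @param wavelengths_nm wavelength grid; defaults to [default_grid()].
#' @param value constant power per nm.
#' @return A power `spectrum`.
#' @export
equal_energy_spectrum <- function(wavelengths_nm = default_grid(), value = 1) {
  spectrum(wavelengths_nm, rep(value, length(wavelengths_nm)), "power")
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation inside the measured range; constant (edge-value)
#' extrapolation outside it. Edge extrapolation is deliberate: printed-surface
#' reflectances measured from 400 nm are extended down to 390 nm this way,
#' where residual cone sensitivity gives the extension negligible weight.
#'
#' @param spec a `spectrum`.
#' @param wavelengths_nm target grid.
#' @return A `spectrum` on the new grid, same `kind`.
#' @export
resample_spectrum <- function(spec, wavelengths_nm = default_grid()) {
  stopifnot(inherits(spec, "spectrum"))
  v <- stats::approx(
    x = spec$wavelengths_nm, y = spec$values, xout = wavelengths_nm,
    method = "linear", rule = 2
  )$y
  spectrum(wavelengths_nm, v, spec$kind)
}

# Put two spectra on a shared grid (the first spectrum's grid), resampling the
# second. Errors if the ranges do not overlap at all.
common_grid <- function(a, b) {
  overlap_lo <- max(min(a$wavelengths_nm), min(b$wavelengths_nm))
  overlap_hi <- min(max(a$wavelengths_nm), max(b$wavelengths_nm))
  if (overlap_lo >= overlap_hi) {
    stop(sprintf(
      "wavelength ranges do not overlap: %g-%g nm vs %g-%g nm",
      min(a$wavelengths_nm), max(a$wavelengths_nm),
      min(b$wavelengths_nm), max(b$wavelengths_nm)
    ), call. = FALSE)
  }
  list(a = a, b = resample_spectrum(b, a$wavelengths_nm))
}

#' Light reflected from a surface
#'
#' Pointwise product of an illuminant power spectrum and a surface
#' reflectance, i.e. the radiance reaching the eye from a matte surface under
#' that light. The surface is resampled onto the light's grid if needed.
#'
#' @param light a power `spectrum`.
#' @param surface a reflectance `spectrum`.
#' @return A power `spectrum` on the light's grid.
#' @export
reflect <- function(light, surface) {
  stopifnot(inherits(light, "spectrum"), inherits(surface, "spectrum"))
  if (light$kind != "power") stop("`light` must be a power spectrum", call. = FALSE)
  if (surface$kind != "reflectance") {
    stop("`surface` must be a reflectance spectrum", call. = FALSE)
  }
  g <- common_grid(light, surface)
  spectrum(g$a$wavelengths_nm, g$a$values * pmin(g$b$values, 1.05), "power")
}

#' Add two power spectra
#'
#' Radiant power is additive: the light at a point lit by two sources is the
#' sum of their spectra. Used for the field receiving sunlight plus skylight.
#'
#' @param a,b power `spectrum` objects.
#' @return A power `spectrum` on `a`'s grid.
#' @export
spectrum_add <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (a$kind != "power" || b$kind != "power") {
    stop("can only add power spectra", call. = FALSE)
  }
  g <- common_grid(a, b)
  spectrum(g$a$wavelengths_nm, g$a$values + g$b$values, "power")
}

#' Scale a spectrum by a nonnegative factor
#' @param spec a `spectrum`.
#' @param k scalar, `k >= 0`.
#' @return A `spectrum` with values multiplied by `k`.
#' @export
spectrum_scale <- function(spec, k) {
  stopifnot(inherits(spec, "spectrum"), is.numeric(k), length(k) == 1L, k >= 0)
  spectrum(spec$wavelengths_nm, spec$values * k, spec$kind)
}
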