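#' Cone excitations of a power spectrum
#'
#' Rectangle-rule spectral integration of a radiance spectrum against the L,
#' M, S cone fundamentals: `L = sum(spec * Lbar) * dl`, likewise M and S.
#' Linear and homogeneous of degree 1 in the spectrum. The fundamentals are
#' resampled onto the spectrum grid if the grids differ.
#'
#' @param spec a power `spectrum`.
#' @param fund a `cone_fundamentals` object; defaults to the bundled
#'   synthetic 2-degree set.
#' @return An object of class `cone_excitations`: list with `L`, `M`, `S`
#'   (arbitrary linear units).
#' @export
cone_excitations <- function(spec, fund = default_fundamentals()) {
  stopifnot(inherits(spec, "spectrum"), inherits(fund, "cone_fundamentals"))
  if (spec$kind != "power") {
    stop("cone excitations are defined for power spectra", call. = FALSE)
  }
  wl <- spec$wavelengths_nm
  if (!isTRUE(all.equal(wl, fund$wavelengths_nm, tolerance = 1e-9))) {
    lo <- max(min(wl), min(fund$wavelengths_nm))
    hi <- min(max(wl), max(fund$wavelengths_nm))
    if (lo >= hi) {
      stop(sprintf(
        "spectrum (%g-%g nm) and fundamentals (%g-%g nm) do not overlap",
        min(wl), max(wl), min(fund$wavelengths_nm), max(fund$wavelengths_nm)
      ), call. = FALSE)
    }
    fL <- stats::approx(fund$wavelengths_nm, fund$Lbar, wl, rule = 2)$y
    fM <- stats::approx(fund$wavelengths_nm, fund$Mbar, wl, rule = 2)$y
    fS <- stats::approx(fund$wavelengths_nm, fund$Sbar, wl, rule = 2)$y
  } else {
    fL <- fund$Lbar; fM <- fund$Mbar; fS <- fund$Sbar
  }
  dl <- wl[2] - wl[1]
  structure(
    list(L = sum(spec$values * fL) * dl,
         M = sum(spec$values * fM) * dl,
         S = sum(spec$values * fS) * dl),
    class = "cone_excitations"
  )
}

#' MacLeod-Boynton chromaticity
#'
#' Projects cone excitations into the MacLeod-Boynton diagram:
#' `l = k_L*L / (k_L*L + k_M*M)` and `s = k_S*S / (k_L*L + k_M*M)`, with
#' luminance proxy `lum = k_L*L + k_M*M`. The constants come from the
#' supplied convention (see [mb_convention()]); under the default convention
#' the equal-energy spectrum maps to `s = 1` exactly. Both coordinates are
#' invariant to uniform scaling of the input spectrum.
#'
#' @param x a `cone_excitations` object or a power `spectrum`.
#' @param convention an `mb_convention`; defaults to the bundled one.
#' @param fund fundamentals used when `x` is a spectrum.
#' @return An object of class `mb_chromaticity`: list with `l`, `s`, `lum`.
#' @export
mb_chromaticity <- function(x, convention = default_mb_convention(),
                            fund = default_fundamentals()) {
  if (inherits(x, "spectrum")) x <- cone_excitations(x, fund)
  stopifnot(inherits(x, "cone_excitations"), inherits(convention, "mb_convention"))
  denom <- convention$k_L * x$L + convention$k_M * x$M
  if (!is.finite(denom) || denom <= 0) {
    stop("weighted L+M luminance must be positive for a chromaticity", call. = FALSE)
  }
  structure(
    list(l = convention$k_L * x$L / denom,
         s = convention$k_S * x$S / denom,
         lum = denom),
    class = "mb_chromaticity"
  )
}

#' CIE xy chromaticity of a power spectrum
#'
#' Standard tristimulus integration against 2-degree color matching
#' functions followed by projective normalization `x = X/(X+Y+Z)`,
#' `y = Y/(X+Y+Z)`.
#'
#' @param spec a power `spectrum`.
#' @param cmf a `cmf` object; defaults to the bundled 2-degree set.
#' @return An object of class `xy_chromaticity`: list with `x`, `y`.
#' @export
xy_chromaticity <- function(spec, cmf = default_cmf()) {
  stopifnot(inherits(spec, "spectrum"), inherits(cmf, "cmf"))
  if (spec$kind != "power") {
    stop("xy chromaticity is defined for power spectra", call. = FALSE)
  }
  XYZ <- tristimulus(spec, cmf)
  total <- sum(XYZ)
  if (!is.finite(total) || total <= 0) {
    stop("X+Y+Z must be positive for a chromaticity", call. = FALSE)
  }
  structure(list(x = XYZ[[1]] / total, y = XYZ[[2]] / total),
            class = "xy_chromaticity")
}

# Raw XYZ tristimulus integration (rectangle rule), resampling the CMFs onto
# the spectrum grid when necessary.
tristimulus <- function(spec, cmf = default_cmf()) {
  wl <- spec$wavelengths_nm
  if (!isTRUE(all.equal(wl, cmf$wavelengths_nm, tolerance = 1e-9))) {
    xb <- stats::approx(cmf$wavelengths_nm, cmf$xbar, wl, rule = 2)$y
    yb <- stats::approx(cmf$wavelengths_nm, cmf$ybar, wl, rule = 2)$y
    zb <- stats::approx(cmf$wavelengths_nm, cmf$zbar, wl, rule = 2)$y
  } else {
    xb <- cmf$xbar; yb <- cmf$ybar; zb <- cmf$zbar
  }
  dl <- wl[2] - wl[1]
  c(X = sum(spec$values * xb) * dl,
    Y = sum(spec$values * yb) * dl,
    Z = sum(spec$values * zb) * dl)
}

#' Photometric luminance of a power spectrum
#'
#' `683 * integral(spec * ybar)`, i.e. cd/m^2 when the spectrum is a radiance
#' in W sr^-1 m^-2 nm^-1. All scene illuminants in the package are expressed
#' on this absolute scale.
#'
#' @inheritParams xy_chromaticity
#' @return Luminance in cd/m^2 (scalar).
#' @export
luminance_cdm2 <- function(spec, cmf = default_cmf()) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$kind != "power") stop("luminance is defined for power spectra", call. = FALSE)
  683 * tristimulus(spec, cmf)[["Y"]]
}
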