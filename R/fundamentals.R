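# Package-level cache for the default observer tables, filled lazily.
.sc_cache <- new.env(parent = emptyenv())

# --- visual pigment template -------------------------------------------------

# Govardovskii et al. (2000) A1 visual-pigment absorbance template
# (alpha band plus beta band), normalized so the alpha-band peak is 1.
# `lmax` is the absorbance peak wavelength in nm; returns absorbance on `wl`.
pigment_template_a1 <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmax_beta <- 189 + 0.315 * lmax
  bw_beta <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmax_beta) / bw_beta)^2)
  pmin(alpha + beta, 1)
}

# Parametric ocular-media models for a 2-degree foveal observer.
# Lens + ocular media optical density: exponential short-wavelength cutoff
# scaled to a density of 1.8 at 400 nm (open-pupil convention).
lens_density <- function(wl) {
  pmax(1.8 * exp(-(wl - 400) / 40), 0)
}

# Macular pigment optical density: single broad Gaussian, peak density 0.35
# at 460 nm (2-degree field), negligible beyond ~550 nm.
macular_density <- function(wl) {
  0.35 * exp(-((wl - 460) / 45)^2)
}

# One corneal cone fundamental in energy units, unit peak.
# Steps: pigment absorbance template -> retinal absorptance through axial
# optical density `dmax` -> filtering by lens and macular pigment ->
# quantal-to-energy conversion (multiply by wavelength) -> peak normalize.
# The L cone is a mixture of the two common ser180/ala180 polymorph pigments.
corneal_fundamental <- function(wl, lmax, dmax, polymorph_shift = NULL,
                                polymorph_weight = 0.56) {
  pre <- 10^(-(lens_density(wl) + macular_density(wl)))
  one <- function(lm) (1 - 10^(-dmax * pigment_template_a1(wl, lm))) * pre * wl
  f <- if (is.null(polymorph_shift)) {
    one(lmax)
  } else {
    polymorph_weight * one(lmax) + (1 - polymorph_weight) * one(lmax - polymorph_shift)
  }
  f / max(f)
}

# Absorbance peak that places the corneal (post-media, energy-unit) peak of a
# fundamental at `target` nm. Sub-sample peak located by quadratic fit.
solve_absorbance_peak <- function(wl, target, dmax, polymorph_shift = NULL) {
  corneal_peak <- function(lm) {
    f <- corneal_fundamental(wl, lm, dmax, polymorph_shift)
    i <- which.max(f)
    if (i == 1L || i == length(f)) return(wl[i])
    wl[i] + (f[i - 1] - f[i + 1]) / (2 * (f[i - 1] - 2 * f[i] + f[i + 1]))
  }
  stats::uniroot(function(lm) corneal_peak(lm) - target,
                 interval = c(target - 45, target + 10), tol = 1e-6)$root
}

#' Synthetic 2-degree cone fundamentals
#'
#' Builds L, M, S corneal spectral sensitivities (energy units, unit peak) of
#' a synthetic 2-degree observer emulating the Stockman-Sharpe fundamentals.
#' The curves are generated analytically - Govardovskii A1 pigment templates
#' seen through parametric lens and macular pigment filters, with the
#' documented L-cone ser/ala polymorph mixture - and calibrated only to the
#' published corneal peak wavelengths (570.2, 542.8, 442.1 nm) and axial
#' optical densities (0.50, 0.50, 0.40). They are a stand-in for the
#' tabulated human fundamentals, accurate at the few-percent level; see the
#' package vignette for the validation against published MacLeod-Boynton
#' anchor values.
#'
#' @param wavelengths_nm wavelength grid; defaults to [default_grid()].
#' @return An object of class `cone_fundamentals`: list with
#'   `wavelengths_nm`, `Lbar`, `Mbar`, `Sbar`, `provenance`.
#' @export
synth_cone_fundamentals <- function(wavelengths_nm = default_grid()) {
  wl <- as.numeric(wavelengths_nm)
  lmL <- solve_absorbance_peak(wl, 570.2, 0.50, polymorph_shift = 3.5)
  lmM <- solve_absorbance_peak(wl, 542.8, 0.50)
  lmS <- solve_absorbance_peak(wl, 442.1, 0.40)
  structure(
    list(
      wavelengths_nm = wl,
      Lbar = corneal_fundamental(wl, lmL, 0.50, polymorph_shift = 3.5),
      Mbar = corneal_fundamental(wl, lmM, 0.50),
      Sbar = corneal_fundamental(wl, lmS, 0.40),
      provenance = "synthetic-stockman-sharpe-2deg (analytic, v1)"
    ),
    class = "cone_fundamentals"
  )
}

#' Synthetic CIE 1931 2-degree color matching functions
#'
#' Piecewise-Gaussian analytic approximation (Wyman, Sloan & Shirley 2013) to
#' the 1931 2-degree standard observer, evaluated on the requested grid. The
#' fit reproduces the tabulated functions to within about 1 percent of peak;
#' the equal-energy spectrum maps to (x, y) within 0.001 of (1/3, 1/3).
#'
#' @param wavelengths_nm wavelength grid; defaults to [default_grid()].
#' @return An object of class `cmf`: list with `wavelengths_nm`, `xbar`,
#'   `ybar`, `zbar`, `provenance`.
#' @export
synth_cmf_1931 <- function(wavelengths_nm = default_grid()) {
  wl <- as.numeric(wavelengths_nm)
  g <- function(x, mu, s1, s2) {
    ifelse(x < mu, exp(-0.5 * ((x - mu) / s1)^2), exp(-0.5 * ((x - mu) / s2)^2))
  }
  structure(
    list(
      wavelengths_nm = wl,
      xbar = 1.056 * g(wl, 599.8, 37.9, 31.0) + 0.362 * g(wl, 442.0, 16.0, 26.7) -
        0.065 * g(wl, 501.1, 20.4, 26.2),
      ybar = 0.821 * g(wl, 568.8, 46.9, 40.5) + 0.286 * g(wl, 530.9, 16.3, 31.1),
      zbar = 1.217 * g(wl, 437.0, 11.8, 36.0) + 0.681 * g(wl, 459.0, 26.0, 13.8),
      provenance = "synthetic-cie1931-2deg (multi-lobe Gaussian fit, v1)"
    ),
    class = "cmf"
  )
}

# --- MacLeod-Boynton convention ---------------------------------------------

#' MacLeod-Boynton convention for a set of cone fundamentals
#'
#' Fixes the constants of the MacLeod-Boynton projection: luminance weights
#' `k_L = 1.980647`, `k_M = 1` (the published convention for unit-peak
#' 2-degree fundamentals, under which luminance is `k_L*L + M`), and the
#' S-axis scale `k_S` chosen so that the equal-energy-white spectrum maps to
#' `s = 1` exactly. `k_S` is recomputed from the supplied fundamentals rather
#' than hardcoded, so the normalization contract holds for any bundled or
#' user-supplied table.
#'
#' @param fund a `cone_fundamentals` object.
#' @return An object of class `mb_convention`: list with `k_L`, `k_M`, `k_S`.
#' @export
mb_convention <- function(fund) {
  stopifnot(inherits(fund, "cone_fundamentals"))
  eew <- equal_energy_spectrum(fund$wavelengths_nm)
  ce <- cone_excitations(eew, fund)
  k_L <- 1.980647
  k_M <- 1
  structure(
    list(k_L = k_L, k_M = k_M, k_S = (k_L * ce$L + k_M * ce$M) / ce$S),
    class = "mb_convention"
  )
}

# --- default observer tables (cached) ---------------------------------------

#' Default observer tables
#'
#' The default cone fundamentals, color matching functions, and
#' MacLeod-Boynton convention used when an operation is called without
#' explicit tables. Computed once per session and cached.
#'
#' @return `default_fundamentals()` a `cone_fundamentals`; `default_cmf()` a
#'   `cmf`; `default_mb_convention()` an `mb_convention`.
#' @export
default_fundamentals <- function() {
  if (is.null(.sc_cache$fund)) .sc_cache$fund <- synth_cone_fundamentals()
  .sc_cache$fund
}

#' @rdname default_fundamentals
#' @export
default_cmf <- function() {
  if (is.null(.sc_cache$cmf)) .sc_cache$cmf <- synth_cmf_1931()
  .sc_cache$cmf
}

#' @rdname default_fundamentals
#' @export
default_mb_convention <- function() {
  if (is.null(.sc_cache$conv)) .sc_cache$conv <- mb_convention(default_fundamentals())
  .sc_cache$conv
}

# --- fixture CSV interface ---------------------------------------------------

#' Read or write observer tables as CSV
#'
#' Versioned fixture interface: a fundamentals CSV has columns
#' `wavelength_nm,Lbar,Mbar,Sbar`, a CMF CSV `wavelength_nm,xbar,ybar,zbar`.
#' The copies bundled under `inst/extdata/` (files suffixed `_synthetic`)
#' are written from [synth_cone_fundamentals()] and [synth_cmf_1931()];
#' tables from other sources (e.g. downloaded standard-observer data) can be
#' loaded through the same readers.
#'
#' @param path CSV file path.
#' @param fund,cmf objects to write.
#' @return Readers return `cone_fundamentals` / `cmf` objects; writers return
#'   `path` invisibly.
#' @export
read_fundamentals_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "Lbar", "Mbar", "Sbar")
  if (!all(need %in% names(d))) {
    stop("fundamentals CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (any(d$Lbar < 0 | d$Mbar < 0 | d$Sbar < 0)) {
    stop("cone sensitivities must be nonnegative", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = d$wavelength_nm, Lbar = d$Lbar, Mbar = d$Mbar,
         Sbar = d$Sbar, provenance = paste0("file:", basename(path))),
    class = "cone_fundamentals"
  )
}

#' @rdname read_fundamentals_csv
#' @export
write_fundamentals_csv <- function(fund, path) {
  stopifnot(inherits(fund, "cone_fundamentals"))
  utils::write.csv(
    data.frame(wavelength_nm = fund$wavelengths_nm, Lbar = fund$Lbar,
               Mbar = fund$Mbar, Sbar = fund$Sbar),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname read_fundamentals_csv
#' @export
read_cmf_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "xbar", "ybar", "zbar")
  if (!all(need %in% names(d))) {
    stop("CMF CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  structure(
    list(wavelengths_nm = d$wavelength_nm, xbar = d$xbar, ybar = d$ybar,
         zbar = d$zbar, provenance = paste0("file:", basename(path))),
    class = "cmf"
  )
}

#' @rdname read_fundamentals_csv
#' @export
write_cmf_csv <- function(cmf, path) {
  stopifnot(inherits(cmf, "cmf"))
  utils::write.csv(
    data.frame(wavelength_nm = cmf$wavelengths_nm, xbar = cmf$xbar,
               ybar = cmf$ybar, zbar = cmf$zbar),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a spectrum CSV
#'
#' Column layout `wavelength_nm,value`, one row per grid point. The kind is
#' not encoded in the file and must be supplied.
#'
#' @param path CSV file path.
#' @param kind `"power"` or `"reflectance"`.
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, kind = c("power", "reflectance")) {
  kind <- match.arg(kind)
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("spectrum CSV must have columns wavelength_nm,value", call. = FALSE)
  }
  spectrum(d$wavelength_nm, d$value, kind)
}

#' @rdname read_spectrum_csv
#' @param spec spectrum to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelengths_nm, value = spec$values),
    path, row.names = FALSE
  )
  invisible(path)
}
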