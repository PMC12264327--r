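# Relative spectral radiance of a Planckian (blackbody) radiator,
# normalized to 1 at 560 nm. Fully analytic; used to span a smooth
# daylight-like basis without tabulated data.
planckian_spd <- function(wavelengths_nm, temp_K) {
  lam <- wavelengths_nm * 1e-9
  c2 <- 1.4388e-2
  v <- lam^-5 / (exp(c2 / (lam * temp_K)) - 1)
  ref <- (560e-9)^-5 / (exp(c2 / (560e-9 * temp_K)) - 1)
  v / ref
}

# Daylight-like linear basis: mean spectrum plus the first two principal
# components of Planckian radiators between 4000 and 25000 K. Spans the
# smooth bluish-to-yellowish family around the daylight locus; cannot reach
# greenish or purplish chromaticities (use the Gaussian-bump basis there).
daylight_like_basis <- function(wavelengths_nm = default_grid()) {
  key <- paste0("dlb", length(wavelengths_nm), wavelengths_nm[1])
  if (!is.null(.sc_cache[[key]])) return(.sc_cache[[key]])
  temps <- seq(4000, 25000, by = 500)
  mat <- vapply(temps, function(T) planckian_spd(wavelengths_nm, T),
                numeric(length(wavelengths_nm)))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  out <- list(wavelengths_nm = wavelengths_nm,
              mean = pc$center,
              pc1 = pc$rotation[, 1],
              pc2 = pc$rotation[, 2])
  .sc_cache[[key]] <- out
  out
}

# Fixed set of broad Gaussian bumps covering the visible range; any
# nonnegative mixture is a valid (smooth, nonnegative) SPD.
gaussian_bump_basis <- function(wavelengths_nm = default_grid(), n_bumps = 12,
                                width_nm = 40) {
  centers <- seq(405, 765, length.out = n_bumps)
  vapply(centers,
         function(mu) exp(-0.5 * ((wavelengths_nm - mu) / width_nm)^2),
         numeric(length(wavelengths_nm)))
}

xy_of_values <- function(values, wavelengths_nm, cmf) {
  xy <- xy_chromaticity(spectrum(wavelengths_nm, values, "power"), cmf)
  c(xy$x, xy$y)
}

#' Synthesize an illuminant to reference chromaticity and luminance targets
#'
#' Reference illuminants are specified only by their
#' 2-degree xy chromaticities and luminances; this generator produces a
#' smooth nonnegative SPD realizing those targets. Near-neutral targets use a
#' daylight-like basis (mean plus two principal components of the Planckian
#' family); strongly non-neutral targets (green, magenta) are outside that
#' family's gamut and use a nonnegative mixture of Gaussian bumps. The
#' returned SPD is scaled so its luminance matches `target_lum` exactly, and
#' its chromaticity is verified to lie within `xy_tol` of the target.
#'
#' @param name illuminant name (e.g. `"sky_blue"`).
#' @param target_xy length-2 numeric, target CIE xy (inside the spectral locus).
#' @param target_lum target luminance, cd/m^2.
#' @param basis `"auto"` (daylight first, bumps as fallback), `"daylight"`,
#'   or `"bumps"`.
#' @param seed integer; seeds the multi-start optimizer restarts.
#' @param wavelengths_nm wavelength grid.
#' @param cmf color matching functions used to evaluate the targets.
#' @param xy_tol acceptance tolerance on the realized chromaticity.
#' @return An object of class `illuminant`: list with `name`, `spd`
#'   (a power `spectrum` in absolute units), `target_xy`, `target_lum`,
#'   `realized_xy`, `realized_lum`, `basis`.
#' @export
make_skylight <- function(name, target_xy, target_lum,
                          basis = c("auto", "daylight", "bumps"), seed = 1L,
                          wavelengths_nm = default_grid(), cmf = default_cmf(),
                          xy_tol = 0.005) {
  basis <- match.arg(basis)
  target_xy <- as.numeric(target_xy)
  stopifnot(length(target_xy) == 2L, all(target_xy > 0), sum(target_xy) < 1,
            target_lum > 0)
  wl <- wavelengths_nm

  fit_daylight <- function() {
    b <- daylight_like_basis(wl)
    obj <- function(p) {
      v <- pmax(b$mean + p[1] * b$pc1 + p[2] * b$pc2, 0)
      if (sum(v) <= 0) return(1e6)
      sum((xy_of_values(v, wl, cmf) - target_xy)^2)
    }
    fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    raw <- b$mean + fit$par[1] * b$pc1 + fit$par[2] * b$pc2
    # fraction of power lost to clipping negative lobes; large values mean
    # the target is outside the smooth daylight family's gamut
    clipped <- sum(pmax(-raw, 0)) / sum(abs(raw))
    structure(pmax(raw, 0), clipped_fraction = clipped)
  }

  fit_bumps <- function() {
    B <- gaussian_bump_basis(wl)
    k <- ncol(B)
    obj <- function(p) {
      v <- as.numeric(B %*% exp(pmin(p, 40)))
      if (!all(is.finite(v)) || sum(v) <= 0) return(1e6)
      sum((xy_of_values(v, wl, cmf) - target_xy)^2)
    }
    best <- NULL
    set.seed(seed)
    for (start in seq_len(4)) {
      p0 <- if (start == 1) rep(0, k) else stats::rnorm(k, 0, 1.5)
      fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-12) break
    }
    as.numeric(B %*% exp(pmin(best$par, 40)))
  }

  achieved <- function(v) sqrt(sum((xy_of_values(v, wl, cmf) - target_xy)^2))

  used_basis <- basis
  v <- switch(basis,
    daylight = {
      v0 <- fit_daylight()
      if (attr(v0, "clipped_fraction") >= 0.02) {
        xy <- xy_of_values(as.numeric(v0), wl, cmf)
        stop(sprintf(
          paste0("illuminant '%s': target (%.3f, %.3f) lies outside the ",
                 "smooth daylight-like family (optimizer reached it only by ",
                 "clipping; achieved xy = (%.4f, %.4f)); use basis = \"bumps\""),
          name, target_xy[1], target_xy[2], xy[1], xy[2]
        ), call. = FALSE)
      }
      as.numeric(v0)
    },
    bumps = fit_bumps(),
    auto = {
      v0 <- fit_daylight()
      ok <- achieved(v0) <= xy_tol / 5 &&
        attr(v0, "clipped_fraction") < 0.02
      used_basis <- if (ok) "daylight" else "bumps"
      if (ok) as.numeric(v0) else fit_bumps()
    }
  )
  err <- achieved(v)
  if (err > xy_tol) {
    xy <- xy_of_values(v, wl, cmf)
    stop(sprintf(
      "illuminant '%s': optimizer reached xy = (%.4f, %.4f), %.4f from target (%.3f, %.3f)",
      name, xy[1], xy[2], err, target_xy[1], target_xy[2]
    ), call. = FALSE)
  }
  spd <- spectrum(wl, v, "power")
  spd <- spectrum_scale(spd, target_lum / luminance_cdm2(spd, cmf))
  xy <- xy_chromaticity(spd, cmf)
  structure(
    list(name = name, spd = spd,
         target_xy = target_xy, target_lum = target_lum,
         realized_xy = c(xy$x, xy$y),
         realized_lum = luminance_cdm2(spd, cmf),
         basis = used_basis),
    class = "illuminant"
  )
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf(
    "<illuminant %s: xy = (%.4f, %.4f), %.3g cd/m^2>\n",
    x$name, x$realized_xy[1], x$realized_xy[2], x$realized_lum
  ))
  invisible(x)
}

#' Reference scene targets for the six named illuminants
#'
#' Chromaticity (CIE 2-degree xy) and luminance targets of the simulated
#' scene: one sunlight and five skylights (white, yellow, blue, magenta,
#' green). The skylights are roughly equiluminant near 3 cd/m^2, an order of
#' magnitude dimmer than the 41.9 cd/m^2 sunlight, which is what makes the
#' cast shadow a strongly different local illumination.
#'
#' @return data.frame with columns `name`, `x`, `y`, `lum_cdm2`.
#' @export
illuminant_targets <- function() {
  data.frame(
    name = c("sun", "sky_white", "sky_yellow", "sky_blue", "sky_magenta",
             "sky_green"),
    x = c(0.339, 0.334, 0.377, 0.259, 0.387, 0.257),
    y = c(0.353, 0.345, 0.379, 0.271, 0.258, 0.395),
    lum_cdm2 = c(41.9, 3.12, 3.14, 3.15, 3.15, 3.00)
  )
}

#' Build all six scene illuminants
#'
#' Runs [make_skylight()] for every row of [illuminant_targets()]. The
#' result is cached per session (the targets are fixed), so repeated calls in
#' simulations and tests are cheap.
#'
#' @param seed optimizer seed.
#' @param cmf color matching functions.
#' @return Named list of `illuminant` objects.
#' @export
scene_illuminants <- function(seed = 1L, cmf = default_cmf()) {
  key <- paste0("scene", seed)
  if (!is.null(.sc_cache[[key]])) return(.sc_cache[[key]])
  tg <- illuminant_targets()
  out <- lapply(seq_len(nrow(tg)), function(i) {
    make_skylight(tg$name[i], c(tg$x[i], tg$y[i]), tg$lum_cdm2[i],
                  basis = "auto", seed = seed, cmf = cmf)
  })
  names(out) <- tg$name
  .sc_cache[[key]] <- out
  out
}

#' Names of the five skylights
#' @return Character vector in the fixed factor order used by presets.
#' @export
skylight_names <- function() {
  c("sky_white", "sky_yellow", "sky_blue", "sky_magenta", "sky_green")
}
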