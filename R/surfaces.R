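#' Generate colored surface reflectances
#'
#' Synthesizes `n` smooth printed-paper-like reflectances emulating the six
#' colored hexagons of the scene: band-limited curves (a low-order random
#' Fourier series squashed through a logistic into `[0.05, 0.9]`) that are
#' mutually distinguishable under sunlight. Distinguishability is enforced as
#' a minimum pairwise Euclidean distance in MacLeod-Boynton (l, s)
#' chromaticity computed under the sun illuminant; candidates are redrawn
#' until the constraint holds.
#'
#' Reflectances are generated on 400--780 nm (the measured range of printed
#' samples) and extended to the 390 nm grid edge by constant extrapolation
#' via [resample_spectrum()].
#'
#' @param n number of surfaces (default 6, names `s1`..`s6`).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param sun an `illuminant` providing the light under which separation is
#'   assessed; defaults to the scene sunlight.
#' @param min_separation minimum pairwise MB (l, s) distance under `sun`.
#' @param max_iter redraw budget before giving up.
#' @param fund,convention colorimetric tables for the separation check.
#' @return Named list of `surface_sample` objects: list with `name`,
#'   `reflectance` (a reflectance `spectrum` on the default grid), `mb_sun`
#'   (MB chromaticity under `sun`).
#' @export
make_surfaces <- function(n = 6, seed = 1L, sun = NULL,
                          min_separation = 0.06, max_iter = 500L,
                          fund = default_fundamentals(),
                          convention = default_mb_convention()) {
  stopifnot(n >= 1, min_separation >= 0)
  if (is.null(sun)) sun <- scene_illuminants()$sun
  wl_meas <- seq(400, 780, by = 1)
  set.seed(seed)

  draw_one <- function() {
    # low-order Fourier series over the measured range, squashed to [0.05, 0.9]
    u <- (wl_meas - 400) / 380
    z <- stats::rnorm(1, 0, 0.8)
    for (h in 1:3) {
      z <- z + stats::rnorm(1, 0, 1.6 / h) * sin(2 * pi * h * u) +
        stats::rnorm(1, 0, 1.6 / h) * cos(2 * pi * h * u)
    }
    r <- 0.05 + 0.85 / (1 + exp(-z))
    resample_spectrum(spectrum(wl_meas, r, "reflectance"), default_grid())
  }

  mb_under_sun <- function(refl) {
    mb <- mb_chromaticity(reflect(sun$spd, refl), convention, fund)
    c(mb$l, mb$s)
  }

  kept <- list()
  kept_mb <- matrix(numeric(0), ncol = 2)
  iter <- 0L
  while (length(kept) < n) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf(
        "could not place %d surfaces with pairwise MB separation >= %g in %d draws",
        n, min_separation, max_iter
      ), call. = FALSE)
    }
    cand <- draw_one()
    mb <- mb_under_sun(cand)
    if (nrow(kept_mb) > 0) {
      d <- sqrt(rowSums((kept_mb - matrix(mb, nrow(kept_mb), 2, byrow = TRUE))^2))
      if (min(d) < min_separation) next
    }
    kept[[length(kept) + 1L]] <- cand
    kept_mb <- rbind(kept_mb, mb)
  }

  out <- lapply(seq_len(n), function(i) {
    structure(
      list(name = paste0("s", i), reflectance = kept[[i]],
           mb_sun = list(l = kept_mb[i, 1], s = kept_mb[i, 2])),
      class = "surface_sample"
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @export
print.surface_sample <- function(x, ...) {
  cat(sprintf("<surface %s: MB under sun l = %.4f, s = %.4f>\n",
              x$name, x$mb_sun$l, x$mb_sun$s))
  invisible(x)
}
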