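#' Axis scaling from white-skylight settings
#'
#' The MacLeod-Boynton diagram is not perceptually uniform, so before
#' computing constancy indices each axis is rescaled by the reciprocal of
#' the standard deviation (sample, n-1) of the observer's settings under the
#' white-skylight reference condition. Scales are computed from the
#' analyzed test field's settings within each lighting-by-outline block.
#' With `scope = "per_observer"` one scale pair is fitted per observer per
#' block; with `scope = "pooled"` the settings of all observers in a block
#' are pooled (the small-trial-count variant) and each observer row carries
#' the common scale.
#'
#' @param settings settings data.frame (see [simulate_settings()]).
#' @param scope `"per_observer"` or `"pooled"`.
#' @param field test field whose settings are scaled (default `"right"`,
#'   the field inside the cast shadow).
#' @param reference_skylight name of the reference condition.
#' @return data.frame of class `axis_scale_table`: columns `observer`
#'   (`"(pooled)"` under pooled scope), `lighting`, `outline`, `scale_l`,
#'   `scale_s`.
#' @export
fit_axis_scale <- function(settings, scope = c("per_observer", "pooled"),
                           field = "right", reference_skylight = "sky_white") {
  scope <- match.arg(scope)
  check_settings_df(settings)
  ref <- settings[settings$skylight == reference_skylight &
                    settings$field == field, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop(sprintf("no '%s' settings for reference skylight '%s'",
                 field, reference_skylight), call. = FALSE)
  }
  keys <- if (scope == "per_observer") {
    c("observer", "lighting", "outline")
  } else {
    c("lighting", "outline")
  }
  # SD with the sample (n-1) convention per observer; the pooled scope uses
  # the classical pooled within-observer SD, sqrt(SS_within / (N - G)), which
  # reduces to each observer's SD when the groups are homogeneous.
  pooled_sd <- function(x, by) {
    ss <- sum(tapply(x, by, function(v) sum((v - mean(v))^2)))
    df <- length(x) - length(unique(by))
    if (df < 1) {
      stop("need >= 2 reference settings per observer for pooled scaling",
           call. = FALSE)
    }
    sqrt(ss / df)
  }
  groups <- unique(ref[keys])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(ref))
    for (k in keys) sel <- sel & ref[[k]] == groups[[k]][i]
    g <- ref[sel, , drop = FALSE]
    if (nrow(g) < 2) {
      stop(sprintf("need >= 2 reference settings per group (got %d for %s)",
                   nrow(g), paste(unlist(groups[i, ]), collapse = "/")),
           call. = FALSE)
    }
    if (scope == "per_observer") {
      sd_l <- stats::sd(g$mb_l)
      sd_s <- stats::sd(g$mb_s)
    } else {
      sd_l <- pooled_sd(g$mb_l, g$observer)
      sd_s <- pooled_sd(g$mb_s, g$observer)
    }
    if (sd_l == 0 || sd_s == 0) {
      stop("degenerate reference settings: zero SD on an axis; ",
           "cannot form an axis scale", call. = FALSE)
    }
    data.frame(
      observer = if (scope == "per_observer") groups$observer[i] else "(pooled)",
      lighting = groups$lighting[i], outline = groups$outline[i],
      scale_l = 1 / sd_l, scale_s = 1 / sd_s,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "scope") <- scope
  class(out) <- c("axis_scale_table", "data.frame")
  out
}

as_mb_vec <- function(x) {
  if (inherits(x, "mb_chromaticity")) return(c(x$l, x$s))
  x <- as.numeric(x)
  stopifnot(length(x) == 2L)
  x
}

#' Vector-angle Brunswick constancy index
#'
#' Quantifies the degree of color constancy from the shift of mean
#' achromatic settings relative to the shift of the test-field illuminant,
#' both expressed in the SD-rescaled MacLeod-Boynton plane. With
#' `a_vec = scale * (setting_colored - setting_white)` and
#' `b_vec = scale * (illum_colored - illum_white)`,
#' the index is `CI = a * cos(theta) / b`, the Brunswick ratio incorporating
#' the angle `theta` between the perceptual and physical shift vectors. It
#' equals the projection form `(a_vec . b_vec) / b^2`: 0 means no constancy,
#' 1 perfect constancy, above 1 over-correction, and anti-correlated shifts
#' give negative values (never clamped).
#'
#' @param mean_setting_colored,mean_setting_white mean MB settings
#'   (`mb_chromaticity` or `(l, s)` vectors) under the colored and the white
#'   reference skylight.
#' @param illum_colored,illum_white MB chromaticities of the test-field
#'   illuminant under the two skylights.
#' @param scale length-2 `(scale_l, scale_s)` axis scales (or one row of an
#'   `axis_scale_table`); both shift vectors are rescaled by the same
#'   factors, so the index is invariant to a common multiple of the scales.
#' @return An object of class `constancy_index`: list with `ci`, `a`, `b`,
#'   `theta` (radians, `NA` when the setting shift is zero), `a_vec`,
#'   `b_vec`, `scale`.
#' @export
constancy_index <- function(mean_setting_colored, mean_setting_white,
                            illum_colored, illum_white, scale = c(1, 1)) {
  if (is.data.frame(scale)) scale <- c(scale$scale_l[1], scale$scale_s[1])
  scale <- as.numeric(scale)
  stopifnot(length(scale) == 2L, all(is.finite(scale)), all(scale > 0))
  a_vec <- scale * (as_mb_vec(mean_setting_colored) - as_mb_vec(mean_setting_white))
  b_vec <- scale * (as_mb_vec(illum_colored) - as_mb_vec(illum_white))
  b <- sqrt(sum(b_vec^2))
  if (b == 0) {
    stop("illuminant shift is zero (b = 0): the white reference skylight ",
         "must be excluded from CI computation", call. = FALSE)
  }
  a <- sqrt(sum(a_vec^2))
  theta <- if (a == 0) NA_real_ else acos(max(-1, min(1, sum(a_vec * b_vec) / (a * b))))
  structure(
    list(ci = sum(a_vec * b_vec) / b^2, a = a, b = b, theta = theta,
         a_vec = a_vec, b_vec = b_vec, scale = scale),
    class = "constancy_index"
  )
}

#' @export
print.constancy_index <- function(x, ...) {
  cat(sprintf("<constancy index: CI = %.4f (a = %.4f, b = %.4f, theta = %s rad)>\n",
              x$ci, x$a, x$b,
              if (is.na(x$theta)) "NA" else sprintf("%.4f", x$theta)))
  invisible(x)
}

#' Constancy-index table for a settings data set
#'
#' The full analysis of a settings table: fits (or accepts) axis scales,
#' then computes one constancy index per observer, lighting-by-outline
#' block, and non-white skylight, for the chosen test field. The white
#' reference skylight never appears as a CI row (its illuminant shift is
#' zero). The per-cell mean CI uses mean settings across repeats; the SE is
#' the standard error across per-repeat indices (each repeat's setting
#' against the mean white reference).
#'
#' @param settings settings data.frame.
#' @param illuminants named illuminant list from [scene_illuminants()]
#'   (used for test-field illuminant chromaticities).
#' @param scaling_scope `"per_observer"` or `"pooled"`; ignored when
#'   `axis_scale` is supplied.
#' @param field `"right"` (default: the field inside the cast shadow) or
#'   `"left"`.
#' @param axis_scale optional explicit `axis_scale_table`, or a length-2
#'   numeric used for every cell (e.g. `c(1, 1)` for unscaled MB space).
#' @param reference_skylight the white reference condition.
#' @param fund,convention colorimetric tables.
#' @return data.frame with columns `observer`, `lighting`, `outline`,
#'   `skylight`, `ci`, `a`, `b`, `theta_rad`, `n_repeats`, `se`.
#' @export
ci_table <- function(settings, illuminants,
                     scaling_scope = c("per_observer", "pooled"),
                     field = "right", axis_scale = NULL,
                     reference_skylight = "sky_white",
                     fund = default_fundamentals(),
                     convention = default_mb_convention()) {
  scaling_scope <- match.arg(scaling_scope)
  check_settings_df(settings)
  sets <- settings[settings$field == field, , drop = FALSE]
  if (nrow(sets) == 0) stop("no settings for field '", field, "'", call. = FALSE)

  unit_scale <- NULL
  if (is.numeric(axis_scale)) {
    unit_scale <- as.numeric(axis_scale)
    stopifnot(length(unit_scale) == 2L)
  } else if (is.null(axis_scale)) {
    axis_scale <- fit_axis_scale(settings, scaling_scope, field,
                                 reference_skylight)
  }

  lookup_scale <- function(ob, lt, ol) {
    if (!is.null(unit_scale)) return(unit_scale)
    t <- axis_scale
    sel <- t$lighting == lt & t$outline == ol &
      (t$observer == ob | t$observer == "(pooled)")
    if (!any(sel)) {
      stop(sprintf("no axis scale for group %s/%s/%s", ob, lt, ol),
           call. = FALSE)
    }
    c(t$scale_l[sel][1], t$scale_s[sel][1])
  }

  illum_mb <- function(lt, sky) {
    cond <- scene_condition(lt, "none", sky, field)
    mb <- mb_chromaticity(
      test_field_light(cond, illuminants$sun, illuminants[[sky]]),
      convention, fund
    )
    c(mb$l, mb$s)
  }

  cells <- unique(sets[sets$skylight != reference_skylight,
                       c("observer", "lighting", "outline", "skylight")])
  if (nrow(cells) == 0) stop("no non-reference skylight settings", call. = FALSE)

  # check every scoped group has its white reference before computing
  groups <- unique(cells[c("observer", "lighting", "outline")])
  has_ref <- vapply(seq_len(nrow(groups)), function(i) {
    any(sets$observer == groups$observer[i] &
          sets$lighting == groups$lighting[i] &
          sets$outline == groups$outline[i] &
          sets$skylight == reference_skylight)
  }, logical(1))
  if (!all(has_ref)) {
    miss <- groups[!has_ref, ]
    stop("missing white-skylight reference settings for group(s): ",
         paste(apply(miss, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ob <- cells$observer[i]; lt <- cells$lighting[i]
    ol <- cells$outline[i]; sky <- cells$skylight[i]
    g <- sets[sets$observer == ob & sets$lighting == lt & sets$outline == ol, ]
    col <- g[g$skylight == sky, ]
    ref <- g[g$skylight == reference_skylight, ]
    sc <- lookup_scale(ob, lt, ol)
    m_col <- c(mean(col$mb_l), mean(col$mb_s))
    m_ref <- c(mean(ref$mb_l), mean(ref$mb_s))
    i_col <- illum_mb(lt, sky)
    i_ref <- illum_mb(lt, reference_skylight)
    cell <- constancy_index(m_col, m_ref, i_col, i_ref, sc)
    per_rep <- vapply(seq_len(nrow(col)), function(k) {
      constancy_index(c(col$mb_l[k], col$mb_s[k]), m_ref, i_col, i_ref, sc)$ci
    }, numeric(1))
    data.frame(
      observer = ob, lighting = lt, outline = ol, skylight = sky,
      ci = cell$ci, a = cell$a, b = cell$b, theta_rad = cell$theta,
      n_repeats = nrow(col),
      se = if (nrow(col) > 1) stats::sd(per_rep) / sqrt(nrow(col)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$observer, out$lighting, out$outline,
            match(out$skylight, skylight_names())), , drop = FALSE]
}
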