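#' Parametric partial-constancy observer
#'
#' A simulated observer performing achromatic settings ("adjust the test
#' field until it looks like a full-white surface under the test
#' illuminant"). The chromatic behavior is a convex interpolation in
#' MacLeod-Boynton space: the mean setting under a condition is
#' `w + d * (i - w)`, where `w` is the observer's internal white point (the
#' white-skylight test-field chromaticity plus a fixed observer bias), `i`
#' the chromaticity of the light actually reaching the test field, and `d`
#' the degree of constancy (0 none, 1 perfect, above 1 over-correction).
#' Under this model the downstream constancy index recovers `d` exactly in
#' the noise-free case, which makes the whole analysis surface analytically
#' checkable.
#'
#' Luminance settings are a fraction `lum_fraction` of the luminance a 100%
#' reflectance surface would have under the test-field light (settings below
#' that theoretical limit, as real observers produce), with multiplicative
#' log-normal repeat noise (median-parameterized).
#'
#' @param id observer identifier.
#' @param constancy degree of constancy `d`; typically in `[0, 1.3]`.
#' @param sigma_l,sigma_s Gaussian repeat noise SD on the MB l and s axes.
#' @param lum_fraction fraction of the theoretical full-white luminance.
#' @param lum_sdlog log-scale SD of luminance repeat noise.
#' @param white_bias length-2 `(l, s)` offset of the internal white point.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(id, constancy, sigma_l = 0.002, sigma_s = 0.04,
                           lum_fraction = 0.65, lum_sdlog = 0.08,
                           white_bias = c(0, 0)) {
  stopifnot(is.numeric(constancy), length(constancy) == 1L)
  if (sigma_l < 0 || sigma_s < 0 || lum_sdlog < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }
  if (lum_fraction <= 0 || lum_fraction > 1) {
    stop("lum_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(id = as.character(id), constancy = constancy,
         sigma_l = sigma_l, sigma_s = sigma_s,
         lum_fraction = lum_fraction, lum_sdlog = lum_sdlog,
         white_bias = as.numeric(white_bias)),
    class = "observer_model"
  )
}

#' Simulate achromatic settings for one condition
#'
#' Draws `n_repeats` settings from an [observer_model()] under one scene
#' condition. The reference skylight (white) defines the observer's internal
#' white point; the test skylight defines the light reaching the test field
#' through [test_field_light()].
#'
#' @param obs an `observer_model`.
#' @param cond a `scene_condition`.
#' @param reference_sky the white-skylight `illuminant`.
#' @param test_sky the `illuminant` of the condition's skylight.
#' @param sun the sunlight `illuminant` (needed for the left field under
#'   `sun_and_sky`).
#' @param n_repeats number of settings (sessions) to draw.
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used
#'   (as when called from [simulate_experiment()]).
#' @param fund,convention,cmf colorimetric tables.
#' @return data.frame with columns `observer`, `lighting`, `outline`,
#'   `skylight`, `field`, `repeat`, `mb_l`, `mb_s`, `lum_cdm2`.
#' @export
simulate_settings <- function(obs, cond, reference_sky, test_sky, sun = NULL,
                              n_repeats = 7L, seed = NULL,
                              fund = default_fundamentals(),
                              convention = default_mb_convention(),
                              cmf = default_cmf()) {
  stopifnot(inherits(obs, "observer_model"), inherits(cond, "scene_condition"),
            n_repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sun) && cond$test_field == "left" && cond$lighting == "sun_and_sky") {
    stop("`sun` is required for the left field under sun_and_sky", call. = FALSE)
  }

  light_test <- test_field_light(cond, sun, test_sky)
  cond_ref <- cond
  cond_ref$skylight <- "sky_white"
  light_ref <- test_field_light(cond_ref, sun, reference_sky)

  i_mb <- mb_chromaticity(light_test, convention, fund)
  w_mb <- mb_chromaticity(light_ref, convention, fund)
  w <- c(w_mb$l, w_mb$s) + obs$white_bias
  mean_set <- w + obs$constancy * (c(i_mb$l, i_mb$s) - w)

  lum0 <- obs$lum_fraction * luminance_cdm2(light_test, cmf)
  n <- as.integer(n_repeats)
  out <- data.frame(
    observer = obs$id,
    lighting = cond$lighting,
    outline = cond$outline,
    skylight = cond$skylight,
    field = cond$test_field,
    rep = seq_len(n),
    mb_l = mean_set[1] + stats::rnorm(n, 0, obs$sigma_l),
    mb_s = mean_set[2] + stats::rnorm(n, 0, obs$sigma_s),
    lum_cdm2 = lum0 * exp(stats::rnorm(n, 0, obs$lum_sdlog)),
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "rep"] <- "repeat"
  out
}

#' Experiment scenario presets
#'
#' Declarative configurations of the three simulated designs:
#' \describe{
#'   \item{`exp1`}{3 observers, 5 skylights, two lighting blocks
#'     (sunlight-plus-skylight and skylight-only), 7 sessions; per-observer
#'     axis scaling; constancy degrees drawn near 1.1 (the high-constancy,
#'     practiced-observer regime).}
#'   \item{`exp2`}{12 observers, 5 skylights, two outline blocks
#'     (no-outline and outlined cast shadow) under sunlight-plus-skylight,
#'     2 sessions; pooled axis scaling; constancy degrees drawn near 0.85.}
#'   \item{`grey_paper_followup`}{the follow-up design with uniform grey
#'     surfaces: as `exp2` but constancy degrees drawn near zero.}
#' }
#'
#' @param name preset name.
#' @return A config list consumable by [simulate_experiment()]; the `seed`
#'   entry is `NULL` and must be set before simulating.
#' @export
scenario_preset <- function(name = c("exp1", "exp2", "grey_paper_followup")) {
  name <- match.arg(name)
  base <- list(
    preset = name,
    skylights = skylight_names(),
    fields = c("left", "right"),
    sigma_l = 0.002, sigma_s = 0.04,
    lum_fraction = 0.65, lum_sdlog = 0.08,
    bias_sd_l = 0.003, bias_sd_s = 0.05,
    d_range = c(0, 1.3),
    seed = NULL
  )
  extra <- switch(name,
    exp1 = list(
      observers = paste0("obs", 1:3),
      lightings = c("sun_and_sky", "sky_only"),
      outlines = "none",
      n_repeats = 7L,
      d_mean = 1.1, d_sd = 0.25,
      scaling_scope = "per_observer"
    ),
    exp2 = list(
      observers = sprintf("obs%02d", 1:12),
      lightings = "sun_and_sky",
      outlines = c("no_outline", "outlined"),
      n_repeats = 2L,
      d_mean = 0.85, d_sd = 0.30,
      scaling_scope = "pooled"
    ),
    grey_paper_followup = list(
      observers = sprintf("obs%02d", 1:12),
      lightings = "sun_and_sky",
      outlines = c("no_outline", "outlined"),
      n_repeats = 2L,
      d_mean = 0, d_sd = 0.05, d_range = c(-0.15, 0.15),
      scaling_scope = "pooled"
    )
  )
  utils::modifyList(base, extra)
}

# Truncated-normal draw by rejection (cheap at these widths).
draw_truncnorm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Run a full simulated experiment
#'
#' Simulates every observer under every block (lighting x outline), skylight,
#' and test field of a config from [scenario_preset()] (or a compatible
#' list). Observer white-point biases are drawn once per observer; a degree
#' of constancy is drawn once per observer per block, modelling the
#' between-block variation real observers show. All randomness flows from
#' the single `seed`, so identical config plus seed gives an identical
#' settings table.
#'
#' @param config preset config; `config$seed` (or the `seed` argument) is
#'   mandatory.
#' @param seed overrides `config$seed`.
#' @param scene named illuminant list from [scene_illuminants()].
#' @param fund,convention,cmf colorimetric tables.
#' @return An object of class `experiment_run`: list with `settings` (the
#'   settings data.frame), `truth` (data.frame of the drawn per-block
#'   constancy degrees and observer biases), and `config`.
#' @export
simulate_experiment <- function(config, seed = config$seed,
                                scene = scene_illuminants(),
                                fund = default_fundamentals(),
                                convention = default_mb_convention(),
                                cmf = default_cmf()) {
  if (is.null(seed)) {
    stop("config schema error: `seed` is mandatory for a stochastic run",
         call. = FALSE)
  }
  config$seed <- as.integer(seed)
  set.seed(config$seed)

  blocks <- expand.grid(lighting = config$lightings, outline = config$outlines,
                        stringsAsFactors = FALSE)
  settings <- list()
  truth <- list()
  for (ob in config$observers) {
    bias <- c(stats::rnorm(1, 0, config$bias_sd_l),
              stats::rnorm(1, 0, config$bias_sd_s))
    for (bi in seq_len(nrow(blocks))) {
      d <- draw_truncnorm(1, config$d_mean, config$d_sd, config$d_range)
      obs <- observer_model(ob, d, config$sigma_l, config$sigma_s,
                            config$lum_fraction, config$lum_sdlog, bias)
      truth[[length(truth) + 1L]] <- data.frame(
        observer = ob, lighting = blocks$lighting[bi],
        outline = blocks$outline[bi], d = d,
        bias_l = bias[1], bias_s = bias[2], stringsAsFactors = FALSE
      )
      for (sky in config$skylights) {
        for (fld in config$fields) {
          cond <- scene_condition(blocks$lighting[bi], blocks$outline[bi],
                                  sky, fld)
          settings[[length(settings) + 1L]] <- simulate_settings(
            obs, cond, scene$sky_white, scene[[sky]], scene$sun,
            n_repeats = config$n_repeats, seed = NULL,
            fund = fund, convention = convention, cmf = cmf
          )
        }
      }
    }
  }
  structure(
    list(settings = do.call(rbind, settings),
         truth = do.call(rbind, truth),
         config = config),
    class = "experiment_run"
  )
}

#' @export
print.experiment_run <- function(x, ...) {
  cat(sprintf(
    "<experiment_run '%s': %d observers, %d settings rows, seed %d>\n",
    x$config$preset %||% "custom", length(unique(x$settings$observer)),
    nrow(x$settings), x$config$seed
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
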