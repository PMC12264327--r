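#' Scene condition
#'
#' One cell of the experimental design: which projectors are on, whether the
#' shadow penumbra is outlined, which skylight color is shown, and which test
#' field is being set. The geometric fact the scene encodes is that the
#' right test field lies inside the cast shadow, so under
#' `lighting = "sun_and_sky"` it still receives skylight only, while the
#' left field receives the sum of sunlight and skylight.
#'
#' @param lighting `"sun_and_sky"` or `"sky_only"`.
#' @param outline `"none"`, `"no_outline"`, or `"outlined"` (the outline
#'   manipulation is purely perceptual and does not change the light).
#' @param skylight one of [skylight_names()].
#' @param test_field `"left"` or `"right"`.
#' @return An object of class `scene_condition`.
#' @export
scene_condition <- function(lighting = c("sun_and_sky", "sky_only"),
                            outline = c("none", "no_outline", "outlined"),
                            skylight = skylight_names(),
                            test_field = c("right", "left")) {
  structure(
    list(lighting = match.arg(lighting), outline = match.arg(outline),
         skylight = match.arg(skylight), test_field = match.arg(test_field)),
    class = "scene_condition"
  )
}

#' Light reaching a test field
#'
#' The right field lies inside the cast shadow: it receives the skylight
#' only, under either lighting. The left field receives sunlight plus
#' skylight when both projectors are on, and skylight only in the
#' skylight-only control.
#'
#' @param cond a `scene_condition`.
#' @param sun,sky `illuminant` objects (or power `spectrum`s).
#' @return A power `spectrum`.
#' @export
test_field_light <- function(cond, sun, sky) {
  stopifnot(inherits(cond, "scene_condition"))
  sun_spd <- if (inherits(sun, "illuminant")) sun$spd else sun
  sky_spd <- if (inherits(sky, "illuminant")) sky$spd else sky
  if (cond$lighting == "sky_only" || cond$test_field == "right") {
    return(sky_spd)
  }
  spectrum_add(sun_spd, sky_spd)
}
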