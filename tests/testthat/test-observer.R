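test_that("noise-free endpoint behavior: d = 1 tracks the illuminant, d = 0 the white point", {
  sc <- the_scene()
  cond <- scene_condition("sun_and_sky", "none", "sky_magenta", "right")
  illum <- mb_chromaticity(test_field_light(cond, sc$sun, sc$sky_magenta))

  perfect <- observer_model("p", 1, sigma_l = 0, sigma_s = 0, lum_sdlog = 0)
  st <- simulate_settings(perfect, cond, sc$sky_white, sc$sky_magenta, sc$sun,
                          n_repeats = 3)
  expect_equal(unique(st$mb_l), illum$l, tolerance = 1e-12)
  expect_equal(unique(st$mb_s), illum$s, tolerance = 1e-12)

  none <- observer_model("z", 0, sigma_l = 0, sigma_s = 0, lum_sdlog = 0,
                         white_bias = c(0.01, -0.05))
  st0 <- simulate_settings(none, cond, sc$sky_white, sc$sky_magenta, sc$sun,
                           n_repeats = 2)
  w <- mb_chromaticity(sc$sky_white$spd)
  expect_equal(unique(st0$mb_l), w$l + 0.01, tolerance = 1e-12)
  expect_equal(unique(st0$mb_s), w$s - 0.05, tolerance = 1e-12)
})

test_that("luminance settings sit at the stated fraction of the full-white limit", {
  sc <- the_scene()
  cond <- scene_condition("sky_only", "none", "sky_green", "right")
  obs <- observer_model("f", 0.8, sigma_l = 0, sigma_s = 0,
                        lum_fraction = 0.55, lum_sdlog = 0)
  st <- simulate_settings(obs, cond, sc$sky_white, sc$sky_green, sc$sun, 2)
  limit <- luminance_cdm2(test_field_light(cond, sc$sun, sc$sky_green))
  expect_equal(unique(st$lum_cdm2), 0.55 * limit, tolerance = 1e-12)
  expect_lt(unique(st$lum_cdm2), limit)
})

test_that("observer constructor rejects invalid noise and fraction", {
  expect_error(observer_model("x", 1, sigma_l = -0.1), "nonnegative")
  expect_error(observer_model("x", 1, lum_fraction = 0), "lum_fraction")
})

test_that("presets encode the experimental designs", {
  e1 <- scenario_preset("exp1")
  expect_length(e1$observers, 3)
  expect_identical(e1$lightings, c("sun_and_sky", "sky_only"))
  expect_identical(e1$n_repeats, 7L)
  expect_identical(e1$scaling_scope, "per_observer")

  e2 <- scenario_preset("exp2")
  expect_length(e2$observers, 12)
  expect_identical(e2$outlines, c("no_outline", "outlined"))
  expect_identical(e2$n_repeats, 2L)

  grey <- scenario_preset("grey_paper_followup")
  expect_length(grey$observers, 12)
  expect_equal(grey$d_mean, 0)

  expect_error(scenario_preset("exp3"), "arg")
})

test_that("simulated experiments are deterministic and have the preset shape", {
  sc <- the_scene()
  cfg <- scenario_preset("exp1")
  r1 <- simulate_experiment(cfg, seed = 9, scene = sc)
  r2 <- simulate_experiment(cfg, seed = 9, scene = sc)
  expect_identical(r1$settings, r2$settings)
  r3 <- simulate_experiment(cfg, seed = 10, scene = sc)
  expect_false(identical(r1$settings$mb_l, r3$settings$mb_l))

  # exp1: 3 observers x 2 lightings x 5 skylights x 2 fields x 7 repeats
  expect_identical(nrow(r1$settings), 3L * 2L * 5L * 2L * 7L)

  cfg2 <- scenario_preset("exp2")
  r4 <- simulate_experiment(cfg2, seed = 1, scene = sc)
  # 12 observers x 5 skylights x 2 outlines x 2 sessions rows per field
  expect_identical(sum(r4$settings$field == "right"), 12L * 5L * 2L * 2L)
  expect_identical(nrow(r4$settings), 2L * 12L * 5L * 2L * 2L)

  expect_error(simulate_experiment(cfg), "seed")
})

test_that("grey-paper follow-up draws constancy near zero", {
  cfg <- scenario_preset("grey_paper_followup")
  run <- simulate_experiment(cfg, seed = 4, scene = the_scene())
  expect_true(all(abs(run$truth$d) <= 0.15))
  expect_lt(abs(mean(run$truth$d)), 0.1)
})
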