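test_that("spectrum constructor enforces grid and value invariants", {
  expect_s3_class(spectrum(390:780, rep(1, 391), "power"), "spectrum")
  expect_error(spectrum(c(400, 399, 401), c(1, 1, 1), "power"), "increasing")
  expect_error(spectrum(c(400, 401, 403), c(1, 1, 1), "power"), "uniform")
  expect_error(spectrum(400:402, c(1, -1, 1), "power"), "nonnegative")
  expect_error(spectrum(400:402, c(0.5, 1.2, 0.5), "reflectance"), "1.05")
  # small printer-gloss tolerance above 1 is accepted for reflectance
  expect_s3_class(spectrum(400:402, c(0.5, 1.04, 0.5), "reflectance"), "spectrum")
  expect_error(spectrum(400:402, c(1, NA, 1), "power"), "finite")
})

test_that("resampling interpolates linearly and extrapolates edge values", {
  s <- spectrum(c(400, 410, 420), c(0, 1, 0), "power")
  r <- resample_spectrum(s, seq(395, 425, by = 5))
  expect_equal(r$values, c(0, 0, 0.5, 1, 0.5, 0, 0))
  # edge-value extension below the measured range (reflectances measured
  # from 400 nm are carried down to 390 nm unchanged)
  refl <- spectrum(seq(400, 780), seq(0.2, 0.6, length.out = 381), "reflectance")
  ext <- resample_spectrum(refl, default_grid())
  expect_equal(ext$values[1:11], rep(0.2, 11))
})

test_that("reflect is the pointwise product with the expected edge cases", {
  sky <- the_scene()$sky_blue$spd
  ones <- spectrum(default_grid(), rep(1, 391), "reflectance")
  zeros <- spectrum(default_grid(), rep(0, 391), "reflectance")
  expect_equal(reflect(sky, ones)$values, sky$values)
  expect_equal(reflect(sky, zeros)$values, rep(0, 391))
  expect_error(reflect(ones, sky), "power")

  # chromaticity of skylight x surface equals the oracle computed from the
  # tabulated pointwise products
  s1 <- the_surfaces()$s1$reflectance
  prod_tab <- sky$values * s1$values
  got <- mb_chromaticity(reflect(sky, s1))
  fund <- default_fundamentals()
  conv <- default_mb_convention()
  L <- loop_integral(prod_tab, fund$Lbar)
  M <- loop_integral(prod_tab, fund$Mbar)
  S <- loop_integral(prod_tab, fund$Sbar)
  expect_equal(got$l, conv$k_L * L / (conv$k_L * L + conv$k_M * M),
               tolerance = 1e-12)
  expect_equal(got$s, conv$k_S * S / (conv$k_L * L + conv$k_M * M),
               tolerance = 1e-12)
})

test_that("power spectra add and scale; disjoint ranges error by name", {
  a <- spectrum(400:500, rep(1, 101), "power")
  b <- spectrum(400:500, seq(0, 1, length.out = 101), "power")
  expect_equal(spectrum_add(a, b)$values, a$values + b$values)
  expect_equal(spectrum_scale(a, 2.5)$values, rep(2.5, 101))
  d <- spectrum(600:700, rep(1, 101), "power")
  expect_error(spectrum_add(a, d), "do not overlap")
})
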