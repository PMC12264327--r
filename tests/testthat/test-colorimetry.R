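test_that("cone excitations are linear and homogeneous", {
  zero <- spectrum(default_grid(), rep(0, 391), "power")
  z <- cone_excitations(zero)
  expect_equal(c(z$L, z$M, z$S), c(0, 0, 0))

  set.seed(42)
  for (k in 1:5) {
    s1 <- random_spectrum()
    s2 <- random_spectrum()
    a <- runif(1, 0, 3)
    b <- runif(1, 0, 3)
    mix <- spectrum(s1$wavelengths_nm, a * s1$values + b * s2$values, "power")
    c1 <- cone_excitations(s1)
    c2 <- cone_excitations(s2)
    cm <- cone_excitations(mix)
    expect_equal(cm$L, a * c1$L + b * c2$L, tolerance = 1e-12)
    expect_equal(cm$M, a * c1$M + b * c2$M, tolerance = 1e-12)
    expect_equal(cm$S, a * c1$S + b * c2$S, tolerance = 1e-12)
  }

  s <- random_spectrum()
  c1 <- cone_excitations(s)
  c2 <- cone_excitations(spectrum_scale(s, 2))
  expect_equal(c2$L / c1$L, 2, tolerance = 1e-12)
})

test_that("spectral integrations agree with a brute-force summation oracle", {
  fund <- default_fundamentals()
  eew <- equal_energy_spectrum()
  ce <- cone_excitations(eew)
  expect_equal(ce$L, loop_integral(eew$values, fund$Lbar), tolerance = 1e-9)

  set.seed(7)
  for (k in 1:20) {
    s <- random_spectrum()
    ce <- cone_excitations(s)
    expect_equal(ce$L, loop_integral(s$values, fund$Lbar), tolerance = 1e-9)
    expect_equal(ce$M, loop_integral(s$values, fund$Mbar), tolerance = 1e-9)
    expect_equal(ce$S, loop_integral(s$values, fund$Sbar), tolerance = 1e-9)
  }
})

test_that("cone excitations error on non-overlapping wavelength ranges", {
  uv <- spectrum(200:300, rep(1, 101), "power")
  expect_error(cone_excitations(uv), "do not overlap")
})

test_that("MacLeod-Boynton projection honors its normalization contract", {
  conv <- default_mb_convention()
  mb <- mb_chromaticity(equal_energy_spectrum())
  expect_equal(mb$s, 1, tolerance = 1e-12)
  expect_gt(mb$l, 0)
  expect_lt(mb$l, 1)

  no_s <- structure(list(L = 2, M = 1, S = 0), class = "cone_excitations")
  expect_equal(mb_chromaticity(no_s)$s, 0)

  dark <- structure(list(L = 0, M = 0, S = 1), class = "cone_excitations")
  expect_error(mb_chromaticity(dark), "positive")

  # scale invariance
  s <- random_spectrum()
  m1 <- mb_chromaticity(s)
  m2 <- mb_chromaticity(spectrum_scale(s, 17.3))
  expect_equal(m1$l, m2$l, tolerance = 1e-12)
  expect_equal(m1$s, m2$s, tolerance = 1e-12)
})

test_that("surface chromaticities under white skylight match the composed-ops oracle", {
  sky <- the_scene()$sky_white$spd
  fund <- default_fundamentals()
  conv <- default_mb_convention()
  for (sf in the_surfaces()) {
    got <- mb_chromaticity(reflect(sky, sf$reflectance), conv, fund)
    ce <- cone_excitations(reflect(sky, sf$reflectance), fund)
    expect_equal(got$l,
                 conv$k_L * ce$L / (conv$k_L * ce$L + conv$k_M * ce$M),
                 tolerance = 1e-12)
  }
})

test_that("xy chromaticity is projective and matches its oracle", {
  eew <- equal_energy_spectrum()
  xy <- xy_chromaticity(eew)
  expect_equal(xy$x, 1 / 3, tolerance = 0.01)
  expect_equal(xy$y, 1 / 3, tolerance = 0.01)

  s <- the_scene()$sky_blue$spd
  xy1 <- xy_chromaticity(s)
  xy2 <- xy_chromaticity(spectrum_scale(s, 123.4))
  expect_equal(xy1$x, xy2$x, tolerance = 1e-12)
  expect_equal(xy1$y, xy2$y, tolerance = 1e-12)

  cmf <- default_cmf()
  X <- loop_integral(s$values, cmf$xbar)
  Y <- loop_integral(s$values, cmf$ybar)
  Z <- loop_integral(s$values, cmf$zbar)
  expect_equal(xy1$x, X / (X + Y + Z), tolerance = 1e-9)
  expect_equal(xy1$y, Y / (X + Y + Z), tolerance = 1e-9)
  expect_equal(luminance_cdm2(s), 683 * Y, tolerance = 1e-9)

  zero <- spectrum(default_grid(), rep(0, 391), "power")
  expect_error(xy_chromaticity(zero), "positive")
})
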