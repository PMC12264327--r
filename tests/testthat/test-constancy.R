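mk_settings <- function(observer, mb_l, mb_s, skylight = "sky_white",
                        lighting = "sun_and_sky", outline = "none",
                        field = "right") {
  n <- length(mb_l)
  out <- data.frame(
    observer = observer, lighting = lighting, outline = outline,
    skylight = skylight, field = field, rep = seq_len(n),
    mb_l = mb_l, mb_s = mb_s, lum_cdm2 = rep(2, n),
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "rep"] <- "repeat"
  out
}

test_that("axis scales are reciprocal sample SDs", {
  # mb_l values with SD exactly 0.5
  s <- mk_settings("o1", c(0.2, 0.7, 1.2) - 0.2, c(1, 2, 3))
  expect_equal(sd(s$mb_l), 0.5)
  sc <- fit_axis_scale(s, "per_observer")
  expect_equal(sc$scale_l, 2)
  expect_equal(sc$scale_s, 1)

  set.seed(31)
  r <- mk_settings("o1", rnorm(9, 0.7, 0.01), rnorm(9, 1, 0.1))
  sc <- fit_axis_scale(r, "per_observer")
  expect_equal(sc$scale_l, 1 / sd(r$mb_l), tolerance = 1e-12)
  expect_equal(sc$scale_s, 1 / sd(r$mb_s), tolerance = 1e-12)
})

test_that("pooled scaling equals per-observer scaling on homogeneous groups", {
  a <- mk_settings("o1", c(0.69, 0.70, 0.71), c(0.9, 1.0, 1.1))
  b <- mk_settings("o2", c(0.69, 0.70, 0.71), c(0.9, 1.0, 1.1))
  both <- rbind(a, b)
  per <- fit_axis_scale(both, "per_observer")
  pooled <- fit_axis_scale(both, "pooled")
  expect_identical(pooled$observer, "(pooled)")
  expect_equal(pooled$scale_l, per$scale_l[1], tolerance = 1e-12)
  expect_equal(pooled$scale_s, per$scale_s[1], tolerance = 1e-12)
})

test_that("degenerate reference settings error rather than give infinite scale", {
  s <- mk_settings("o1", c(0.7, 0.7, 0.7), c(1, 2, 3))
  expect_error(fit_axis_scale(s, "per_observer"), "zero SD")
  one <- mk_settings("o1", 0.7, 1)
  expect_error(fit_axis_scale(one, "per_observer"), ">= 2")
})

test_that("constancy index endpoints and oracle agreement", {
  w <- c(0.70, 1.00)
  iw <- c(0.70, 1.00)
  ic <- c(0.69, 1.40)

  # settings shift equal to illuminant shift: perfect constancy
  expect_equal(constancy_index(ic, w, ic, iw)$ci, 1, tolerance = 1e-12)
  # no settings shift: zero constancy, angle undefined
  z <- constancy_index(w, w, ic, iw)
  expect_equal(z$ci, 0)
  expect_true(is.na(z$theta))
  # orthogonal shift: zero index despite a > 0
  b_vec <- ic - iw
  perp <- w + c(-b_vec[2], b_vec[1])
  expect_equal(constancy_index(perp, w, ic, iw)$ci, 0, tolerance = 1e-12)
  # doubled shift: over-correction, CI = 2
  expect_equal(constancy_index(w + 2 * b_vec, w, ic, iw)$ci, 2,
               tolerance = 1e-12)
  # anti-correlated shift: negative, not clamped
  expect_equal(constancy_index(w - b_vec, w, ic, iw)$ci, -1, tolerance = 1e-12)

  # a cos(theta) / b equals the projection form on random vector pairs
  set.seed(5)
  for (k in 1:1000) {
    a_vec <- rnorm(2)
    b_vec <- rnorm(2)
    if (sqrt(sum(b_vec^2)) < 1e-6) next
    res <- constancy_index(a_vec, c(0, 0), b_vec, c(0, 0))
    via_angle <- res$a * cos(res$theta) / res$b
    via_dot <- sum(a_vec * b_vec) / sum(b_vec^2)
    expect_equal(via_angle, via_dot, tolerance = 1e-12)
    expect_equal(res$ci, via_dot, tolerance = 1e-12)
  }
})

test_that("the index is invariant to a common rescaling of both axes", {
  set.seed(8)
  for (k in 1:50) {
    sc <- exp(rnorm(2))
    kf <- runif(1, 0.1, 10)
    m_c <- rnorm(2); m_w <- rnorm(2); i_c <- rnorm(2); i_w <- c(0, 0)
    ci1 <- constancy_index(m_c, m_w, i_c, i_w, sc)$ci
    ci2 <- constancy_index(m_c, m_w, i_c, i_w, kf * sc)$ci
    expect_equal(ci1, ci2, tolerance = 1e-9)
  }
})

test_that("white reference exclusion: b = 0 errors", {
  expect_error(constancy_index(c(0.7, 1.1), c(0.7, 1.0), c(0.7, 1), c(0.7, 1)),
               "excluded")
})

test_that("noise-free simulated observers recover d exactly in the CI table", {
  run <- noise_free_run(0.7)
  ci <- ci_table(run$settings, the_scene(), axis_scale = c(1, 1))
  expect_equal(nrow(ci), 3 * 4 * 2)  # observers x non-white skylights x lightings
  expect_true(all(abs(ci$ci - 0.7) < 1e-9))
  # the white skylight never appears as a CI row
  expect_false("sky_white" %in% ci$skylight)
})

test_that("duplicate settings rows leave the CI unchanged", {
  run <- noise_free_run(0.9, seed = 5)
  ci1 <- ci_table(run$settings, the_scene(), axis_scale = c(1, 1))
  ci2 <- ci_table(rbind(run$settings, run$settings), the_scene(),
                  axis_scale = c(1, 1))
  expect_equal(ci2$ci, ci1$ci, tolerance = 1e-12)
  expect_identical(ci2$n_repeats, 2L * ci1$n_repeats)
})

test_that("a missing white reference is reported with its group", {
  run <- noise_free_run(0.5, seed = 6)
  s <- run$settings
  s <- s[!(s$skylight == "sky_white" & s$observer == "obs2" &
             s$lighting == "sky_only"), ]
  expect_error(ci_table(s, the_scene(), axis_scale = c(1, 1)),
               "obs2/sky_only")
})

test_that("the exp1 design yields the full 3 x 4 x 2 CI table with SEs", {
  cfg <- scenario_preset("exp1")
  run <- simulate_experiment(cfg, seed = 13, scene = the_scene())
  ci <- ci_table(run$settings, the_scene(), scaling_scope = "per_observer")
  expect_equal(nrow(ci), 3 * 4 * 2)
  expect_true(all(is.finite(ci$se)))
  expect_true(all(ci$n_repeats == 7L))
  expect_true(all(ci$b > 0))
  expect_true(all(ci$theta_rad >= 0 & ci$theta_rad <= pi))
})
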