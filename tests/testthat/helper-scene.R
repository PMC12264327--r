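# Shared fixtures, built once per test run (scene_illuminants() itself
# memoizes inside the package, so these are cheap on reuse).

the_scene <- function() scene_illuminants(seed = 1L)

the_surfaces <- function() {
  if (!exists(".helper_surfaces", envir = globalenv())) {
    assign(".helper_surfaces", make_surfaces(n = 6, seed = 7), envir = globalenv())
  }
  get(".helper_surfaces", envir = globalenv())
}

# Brute-force rectangle-rule integration written as an explicit loop,
# independent of the vectorized package path.
loop_integral <- function(values_a, values_b, dl = 1) {
  total <- 0
  for (i in seq_along(values_a)) total <- total + values_a[i] * values_b[i]
  total * dl
}

# A reproducible random smooth power spectrum on the default grid.
random_spectrum <- function() {
  wl <- default_grid()
  u <- (wl - 390) / 390
  z <- rnorm(1, 1, 0.3)
  for (h in 1:4) {
    z <- z + rnorm(1, 0, 0.5 / h) * sin(2 * pi * h * u) +
      rnorm(1, 0, 0.5 / h) * cos(2 * pi * h * u)
  }
  spectrum(wl, exp(z), "power")
}

# Noise-free observer settings for a full exp1-style design at constancy d.
noise_free_run <- function(d, seed = 3L) {
  cfg <- scenario_preset("exp1")
  cfg$d_mean <- d
  cfg$d_sd <- 0
  cfg$d_range <- c(d - 1e-9, d + 1e-9)
  cfg$sigma_l <- 0
  cfg$sigma_s <- 0
  cfg$lum_sdlog <- 0
  simulate_experiment(cfg, seed = seed, scene = the_scene())
}
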