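# numerical CDF oracle for the t distribution: quadrature over the density
t_tail_quadrature <- function(t, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = abs(t), upper = Inf,
                   rel.tol = 1e-10)$value
}

test_that("paired t: anchors, hand-computed example, quadrature p", {
  r <- paired_t_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 2L)

  # hand-computed: d = (1, 2, 2), mean 5/3, sd = sqrt(1/3), t = 5 exactly
  r <- paired_t_two_tailed(c(1, 2, 3), c(0, 0, 1))
  expect_equal(r$t, 5, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * t_tail_quadrature(5, 2), tolerance = 1e-8)

  # the two-sided p at t = 0.847, df = 2 against the quadrature oracle
  expect_equal(2 * stats::pt(0.847, 2, lower.tail = FALSE),
               2 * t_tail_quadrature(0.847, 2), tolerance = 1e-6)

  expect_error(paired_t_two_tailed(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_t_two_tailed(1, 1), "length")
})

test_that("Welch t: anchors, reduction to Student t, formula oracle", {
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)

  # equal variances and sizes: Welch statistic equals the pooled Student t
  x <- c(1.1, 2.3, 2.9, 4.2)
  y <- c(0.6, 1.9, 3.0, 3.5)
  student <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(welch_t(x, y)$t, unname(student$statistic), tolerance = 1e-12)

  set.seed(21)
  for (k in 1:20) {
    x <- rnorm(sample(3:9, 1))
    y <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    r <- welch_t(x, y)
    nx <- length(x); ny <- length(y)
    vx <- var(x) / nx; vy <- var(y) / ny
    t_or <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df_or <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
    expect_equal(r$t, t_or, tolerance = 1e-10)
    expect_equal(r$df, df_or, tolerance = 1e-10)
    expect_equal(r$p, 2 * stats::pt(abs(t_or), df_or, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(r$df_rounded, round(df_or))
  }
})

# independent textbook sums-of-squares decomposition for a fully
# within-subject two-way design, coded directly from the marginal means
rm_anova_oracle <- function(d) {
  nS <- nlevels(d$S); nA <- nlevels(d$A); nB <- nlevels(d$B)
  gm <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mS <- tapply(d$y, d$S, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  mAS <- tapply(d$y, list(d$A, d$S), mean)
  mBS <- tapply(d$y, list(d$B, d$S), mean)
  ss_A <- nS * nB * sum((mA - gm)^2)
  ss_B <- nS * nA * sum((mB - gm)^2)
  ss_S <- nA * nB * sum((mS - gm)^2)
  ss_AB <- nS * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_AS <- nB * sum((mAS - outer(mA - gm, mS - gm, "+") - gm)^2)
  ss_BS <- nA * sum((mBS - outer(mB - gm, mS - gm, "+") - gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_ABS <- ss_tot - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS
  list(
    F_A = (ss_A / (nA - 1)) / (ss_AS / ((nA - 1) * (nS - 1))),
    F_B = (ss_B / (nB - 1)) / (ss_BS / ((nB - 1) * (nS - 1))),
    F_AB = (ss_AB / ((nA - 1) * (nB - 1))) /
      (ss_ABS / ((nA - 1) * (nB - 1) * (nS - 1))),
    ss = c(ss_A, ss_B, ss_AB)
  )
}

rand_design <- function(nS, nA = 4, nB = 2, effect = 0.3) {
  d <- expand.grid(S = factor(seq_len(nS)), A = factor(letters[seq_len(nA)]),
                   B = factor(c("u", "v")[seq_len(nB)]))
  d$y <- rnorm(nrow(d)) + effect * as.integer(d$A) +
    0.2 * as.integer(d$B) * as.integer(d$A)
  names(d) <- c("observer", "skylight", "outline", "ci")
  d
}

test_that("two-way RM ANOVA matches the independent SS oracle", {
  set.seed(77)
  for (k in 1:10) {
    d <- rand_design(nS = sample(4:12, 1))
    got <- rm_anova_two_way(d)
    ora <- rm_anova_oracle(data.frame(y = d$ci, S = d$observer,
                                      A = d$skylight, B = d$outline))
    expect_equal(got$F, c(ora$F_A, ora$F_B, ora$F_AB), tolerance = 1e-8)
    expect_equal(got$ss, ora$ss, tolerance = 1e-8)
  }
})

test_that("RM ANOVA reports the conventional df pattern for 12 x 4 x 2", {
  set.seed(3)
  d <- rand_design(nS = 12)
  got <- rm_anova_two_way(d)
  expect_identical(got$effect, c("skylight", "outline", "skylight:outline"))
  expect_equal(got$df1, c(3, 1, 3))
  expect_equal(got$df2, c(33, 11, 33))
})

test_that("RM ANOVA degenerate and malformed inputs", {
  d <- rand_design(nS = 5)
  d$ci <- 1
  got <- rm_anova_two_way(d)
  expect_equal(got$F, c(0, 0, 0))
  expect_equal(got$p, c(1, 1, 1))

  d2 <- rand_design(nS = 5)
  d2 <- d2[-1, ]
  expect_error(rm_anova_two_way(d2), "complete and balanced")
  expect_error(rm_anova_two_way(d2[0, ]), "complete|missing|level")
})
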