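test_that("Bell rate has the right zero-force limit and force sensitivity", {
  env <- env_at(23)
  p <- rate_params(2.5, 1.5)
  expect_equal(bell_rate(0, p, env), 2.5)
  # unit exponent: delta_x numerically equal to kBT gives a factor e at 1 pN
  pe <- rate_params(1, env$kBT)
  expect_equal(bell_rate(1, pe, env), exp(1))
  # algebraic ratio identity between two forces
  expect_equal(bell_rate(2.9, p, env) / bell_rate(1.7, p, env),
               exp(1.2 * p$delta_x / env$kBT))
  # looping branch: negative delta_x decelerates with force
  pl <- rate_params(10, -5)
  expect_true(all(diff(bell_rate(0:5, pl, env)) < 0))
  expect_error(bell_rate(-1, p, env), "non-negative")
})

test_that("Bell fit inverts bell_rate exactly on noiseless data", {
  env <- env_at(23)
  truth <- rate_params(0.003, 2.2)
  f <- c(2, 5, 8, 11, 14)
  fit <- fit_bell(f, bell_rate(f, truth, env), env)
  expect_equal(fit$k0, truth$k0, tolerance = 1e-10)
  expect_equal(fit$delta_x, truth$delta_x, tolerance = 1e-10)
  expect_error(fit_bell(2, 1, env), "distinct forces")
  expect_error(fit_bell(c(1, 2), c(1, -1), env), "positive")
})

test_that("two printed looping rates give the closed-form two-point solution", {
  env <- env_at(23)
  fit <- fit_bell(c(1.7, 2.9), c(0.58, 0.01), env)
  slope <- (log(0.01) - log(0.58)) / (2.9 - 1.7)
  k0 <- exp(log(0.58) - slope * 1.7)
  expect_equal(fit$delta_x, slope * env$kBT, tolerance = 1e-12)
  expect_equal(fit$k0, k0, tolerance = 1e-12)
  # the numbers themselves: strongly force-inhibited formation
  expect_equal(fit$delta_x, -13.8, tolerance = 0.005)
  expect_equal(fit$k0, 180, tolerance = 0.05)
})

test_that("Bell fit recovers parameters from noisy rates", {
  env <- env_at(23)
  truth <- rate_params(180, -13.8)
  f <- c(1.7, 2.1, 2.5, 2.9)
  set.seed(11)
  dx_ok <- 0; lk0 <- numeric(100)
  for (i in 1:100) {
    noisy <- bell_rate(f, truth, env) * exp(rnorm(4, 0, 0.05))
    fit <- fit_bell(f, noisy, env)
    if (abs(fit$delta_x - truth$delta_x) / abs(truth$delta_x) < 0.1)
      dx_ok <- dx_ok + 1
    lk0[i] <- log(fit$k0)
  }
  expect_gte(dx_ok, 90)
  # zero-force extrapolation is unbiased on the log scale
  expect_equal(mean(lk0), log(truth$k0), tolerance = 0.05 / log(truth$k0))
})

test_that("rupture-force density is normalised with the closed-form mode", {
  env <- env_at(23)
  par <- abzip_rupture_params()
  pro <- loading_protocol(1, f_start = 0, f_end = 40)
  total <- integrate(function(f) rupture_force_pdf(f, pro, par, env),
                     0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # analytic mode sits at the argmax of the density
  mode <- modal_rupture_force(pro, par, env)
  grid <- seq(0.1, 30, by = 0.001)
  dens <- rupture_force_pdf(grid, pro, par, env)
  expect_equal(grid[which.max(dens)], mode, tolerance = 1e-3)
  # mode grows by kBT/dx * log(25) from 0.2 to 5 pN/s
  m1 <- modal_rupture_force(loading_protocol(0.2, f_end = 40), par, env)
  m2 <- modal_rupture_force(loading_protocol(5, f_end = 40), par, env)
  expect_equal(m2 - m1, env$kBT / par$delta_x * log(25), tolerance = 1e-10)
  expect_error(rupture_force_pdf(5, pro, rate_params(1, -2), env),
               "delta_x > 0")
})

test_that("lifetime estimator reproduces the degenerate sample and its SE", {
  fit <- fit_exponential_lifetime(rep(10, 101))
  expect_equal(fit$tau, 10)
  expect_equal(fit$se, 10 / sqrt(100))
  expect_equal(fit$se, 1.0)
  expect_error(fit_exponential_lifetime(5), "two dwell")
  expect_error(fit_exponential_lifetime(c(1, -2)), "positive")
})

test_that("MLE and histogram-fit lifetimes agree on exponential data", {
  set.seed(7)
  rel <- replicate(20, {
    dwells <- rexp(100, 1 / 30)
    m <- fit_exponential_lifetime(dwells, method = "mle")
    h <- fit_exponential_lifetime(dwells, method = "histogram")
    abs(h$tau - m$tau) / m$tau
  })
  # binned least squares carries binning noise on top of the MLE; typical
  # agreement at n = 100 is within 15%
  expect_lt(median(rel), 0.15)
  d <- rexp(100, 1 / 30)
  expect_equal(fit_exponential_lifetime(d)$tau, mean(d))
})

test_that("looping probability follows the two-state closed form", {
  r <- two_state_rates(0.58, 0.01)
  expect_equal(looping_probability(0, r), 0)
  plateau <- 0.58 / 0.59
  expect_equal(looping_probability(1e6, r), plateau)
  expect_equal(looping_probability(5, r),
               plateau * (1 - exp(-0.59 * 5)))
  expect_equal(looping_probability(5, r), 0.932, tolerance = 1e-3)
  dts <- seq(0, 50, by = 1)
  P <- looping_probability(dts, r)
  expect_true(all(diff(P) >= 0))
  expect_true(all(P <= plateau + 1e-12))
})

test_that("looping fit recovers noiseless rates and flags bad designs", {
  dts <- c(2, 5, 10, 20, 40, 80)
  truth <- two_state_rates(0.2, 0.01)
  P <- looping_probability(dts, truth)
  fit <- fit_looping(dts, P)
  expect_equal(fit$rates$k_p, 0.2, tolerance = 1e-6)
  expect_equal(fit$rates$k_u, 0.01, tolerance = 1e-4)
  expect_false(fit$ill_conditioned)
  expect_equal(fit$plateau, fit$rates$k_p / (fit$rates$k_p + fit$rates$k_u))
  # permutation invariance
  o <- c(4, 1, 6, 3, 2, 5)
  fit2 <- fit_looping(dts[o], P[o])
  expect_equal(fit2$rates$k_p, fit$rates$k_p, tolerance = 1e-8)
  # no point beyond one relaxation time: plateau unidentified
  short <- fit_looping(c(0.5, 1, 2), looping_probability(c(0.5, 1, 2), truth))
  expect_true(short$ill_conditioned)
  expect_error(fit_looping(c(1, 2), c(0.1, 0.2)), ">= 3")
  expect_error(fit_looping(dts, rep(0, 6)), "all-zero")
})

test_that("looping recovery under binomial noise is near-unbiased at the
           information limit", {
  # 6 points, 100 cycles/point: the binomial Cramer-Rao floor puts the
  # total-rate relative SD near 12-15%, so individual replicates scatter
  # accordingly; the estimator must be centred on the truth.
  truth <- two_state_rates(0.01, 0.01)
  dts <- c(15, 35, 75, 150, 300, 600)
  set.seed(19)
  est <- replicate(60, {
    P <- rbinom(6, 100, looping_probability(dts, truth)) / 100
    fit <- fit_looping(dts, P, n_cycles = 100)
    c(fit$rates$k_p, fit$rates$k_u)
  })
  expect_equal(median(est[1, ]), 0.01, tolerance = 0.05)
  expect_equal(median(est[2, ]), 0.01, tolerance = 0.10)
  expect_lt(median(abs(est[1, ] - 0.01) / 0.01), 0.20)
})

test_that("rupture mixture decomposition is deterministic and labelled by
           strength", {
  set.seed(3)
  x <- c(rnorm(350, 20, 2), rnorm(150, 12, 2))
  fit <- fit_rupture_mixture(x, 2, n_boot = 50, seed = 1)
  expect_gt(fit$strong[["mean"]], fit$weak[["mean"]])
  expect_equal(fit$weight_strong, 0.7, tolerance = 0.07)
  expect_true(fit$converged)
  # permuting the input changes nothing
  fit2 <- fit_rupture_mixture(sample(x), 2, n_boot = 0)
  expect_equal(fit2$weight_strong, fit$weight_strong, tolerance = 1e-6)
  expect_equal(fit2$strong[["mean"]], fit$strong[["mean"]], tolerance = 1e-6)
  # single component: everything is "strong"
  one <- fit_rupture_mixture(rnorm(100, 15, 1), 1)
  expect_equal(one$weight_strong, 1)
  expect_error(fit_rupture_mixture(rnorm(10), 2), ">= 20")
})

test_that("mixture fit agrees with an independent EM implementation", {
  suppressMessages(library(mclust))
  set.seed(5)
  x <- c(rnorm(300, 21, 2), rnorm(200, 13, 2.5))
  fit <- fit_rupture_mixture(x, 2, n_boot = 0)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  w_strong_mc <- mc$parameters$pro[which.max(mc$parameters$mean)]
  expect_equal(fit$weight_strong, w_strong_mc, tolerance = 0.02)
  expect_equal(fit$strong[["mean"]], max(mc$parameters$mean),
               tolerance = 0.02)
})
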