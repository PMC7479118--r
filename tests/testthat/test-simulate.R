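clamp_fixture_config <- function(seed = 5, ...) {
  tandem_sim_config(4, i27_domain(), unfold = rate_params(0.005, 0.6),
                    env = env_at(23), seed = seed, ...)
}

test_that("identical configuration and seed give bit-identical trajectories", {
  cfg <- clamp_fixture_config()
  a <- simulate_clamp(cfg, 8, 50, seed = 3)
  b <- simulate_clamp(cfg, 8, 50, seed = 3)
  expect_identical(a$extension_nm, b$extension_nm)
  expect_identical(attr(a, "events"), attr(b, "events"))
  pro <- loading_protocol(1, f_start = 1, f_end = 25)
  r1 <- simulate_ramp(looping_sim_config(seed = 1), pro, seed = 9)
  r2 <- simulate_ramp(looping_sim_config(seed = 1), pro, seed = 9)
  expect_identical(r1$rupture_force, r2$rupture_force)
  expect_identical(r1$trajectory$extension_nm, r2$trajectory$extension_nm)
})

test_that("a construct with no possible transition stays at one level", {
  cfg <- tandem_sim_config(2, i27_domain(),
                           unfold = rate_params(1e-300, 0.1),
                           env = env_at(23), seed = 1)
  # rate numerically zero at the clamp force
  tr <- simulate_clamp(cfg, 8, 100, seed = 2)
  expect_equal(nrow(attr(tr, "events")), 0)
  expect_true(all(tr$n_unfolded == 0))
  level <- state_extension(
    construct_state(c(list(handle_params()),
                      rep(list(i27_domain()$folded), 2))), 8, env_at(23))
  expect_equal(mean(tr$extension_nm), level, tolerance = 0.01)
  expect_gt(sd(tr$extension_nm), 1)   # bead noise is present
})

test_that("event-log step sizes equal the polymer-model predictions exactly", {
  cfg <- clamp_fixture_config()
  tr <- simulate_clamp(cfg, 8, 2000, seed = 17)
  ev <- attr(tr, "events")
  expect_gt(nrow(ev), 0)
  i27 <- i27_domain()
  pred <- step_size_curve(
    construct_state(list(i27$folded)),
    construct_state(list(i27$unfolded)), 8, env_at(23))$step_nm
  expect_equal(ev$step_nm, rep(pred, nrow(ev)))
})

test_that("irreversible tandem unfolding gives 4 events with exponential
           first-passage", {
  cfg <- clamp_fixture_config(noise_sd = 0, sampling_rate = 2)
  k_each <- bell_rate(8, rate_params(0.005, 0.6), env_at(23))
  first <- numeric(200)
  for (i in 1:200) {
    tr <- simulate_clamp(cfg, 8, 3000, seed = 400 + i)
    ev <- attr(tr, "events")
    expect_equal(nrow(ev), 4)
    expect_true(all(ev$direction == "unfold"))
    first[i] <- ev$time_s[1]
  }
  ks <- ks.test(first, pexp, rate = 4 * k_each)
  expect_gt(ks$p.value, 0.01)
})

test_that("equilibrium hopping occupancies follow the binomial prediction", {
  cfg <- tandem_sim_config(4, i27_domain(),
                           unfold = rate_params(0.108, 0),
                           refold = rate_params(0.292, 0),
                           env = env_at(37), seed = 2,
                           noise_sd = 0, sampling_rate = 1)
  tr <- simulate_clamp(cfg, 3.5, 10000, seed = 31)
  emp <- as.numeric(table(factor(tr$n_unfolded, levels = 0:4)) / nrow(tr))
  expect_lt(max(abs(emp - binomial_occupancy(0:4, 4, 0.27))), 0.02)
})

test_that("ramp sampler matches the analytic first-passage distribution", {
  env <- env_at(23)
  par <- abzip_rupture_params()
  pro <- loading_protocol(1, f_start = 1, f_end = 40)
  f <- sample_rupture_forces(2000, pro, par, env, seed = 12)
  expect_true(all(!is.na(f)))
  ks <- ks.test(f, oracle_rupture_cdf, k0 = par$k0, dx = par$delta_x,
                kBT = env$kBT, rate = 1, f0 = 1)
  expect_gt(ks$p.value, 0.01)
  # two seed streams: same distribution, different values
  f2 <- sample_rupture_forces(2000, pro, par, env, seed = 13)
  expect_false(any(f[1:50] == f2[1:50]))
  expect_gt(ks.test(f, f2)$p.value, 0.01)
  # vanishing rate never ruptures inside the window
  none <- sample_rupture_forces(100, loading_protocol(1, f_end = 30),
                                rate_params(1e-30, 0.1), env, seed = 1)
  expect_true(all(is.na(none)))
})

test_that("full ramp simulation reports the loop rupture with censoring", {
  cfg <- looping_sim_config(seed = 2)
  pro <- loading_protocol(1, f_start = 1, f_end = 25)
  rr <- simulate_ramp(cfg, pro, seed = 14)
  expect_false(rr$censored)
  expect_true(rr$rupture_force > 1 && rr$rupture_force < 25)
  ev <- rr$events
  expect_equal(ev$force_pN[ev$unit == "loop"], rr$rupture_force)
  # the trace jumps by the predicted step at the rupture force
  st <- looping_construct_states()
  pred <- state_extension(st$unlooped, rr$rupture_force, env_at(23)) -
          state_extension(st$looped, rr$rupture_force, env_at(23))
  expect_equal(ev$step_nm[ev$unit == "loop"], pred, tolerance = 1e-6)
  # a window ending before typical rupture forces censors
  low <- simulate_ramp(cfg, loading_protocol(1, f_start = 1, f_end = 2),
                       seed = 14)
  expect_true(low$censored)
  expect_true(is.na(low$rupture_force))
})

test_that("looping cycles reproduce the closed-form pairing probability", {
  r <- two_state_rates(0.58, 0.01)
  zero <- simulate_looping_cycles(r, 0, 200, seed = 1)
  expect_false(any(zero$looped))
  all_loop <- simulate_looping_cycles(two_state_rates(0.5, 0), 100, 200,
                                      seed = 2)
  expect_true(all(all_loop$looped))
  cyc <- simulate_looping_cycles(r, 5, 4000, seed = 3)
  expect_equal(mean(cyc$looped), looping_probability(5, r),
               tolerance = 0.015 / 0.93)
})

test_that("boxcar smoothing reduces white noise by sqrt(window) and keeps
           edges in place", {
  set.seed(4)
  x <- rnorm(20000, 0, 6)
  sm <- boxcar_smooth(x, 20)
  expect_equal(sd(x) / sd(sm[100:19900]), sqrt(20), tolerance = 0.15)
  expect_identical(boxcar_smooth(x, 1), x)
  expect_error(boxcar_smooth(x[1:10], 11), "exceeds")
  # a clean step's midpoint crossing stays within half a window
  step <- c(rep(0, 500), rep(10, 500))
  sms <- boxcar_smooth(step, 21)
  expect_lt(abs(min(which(sms > 5)) - 501), 11)
})

test_that("apply_smoothing preserves the raw channel", {
  cfg <- clamp_fixture_config()
  tr <- simulate_clamp(cfg, 8, 20, seed = 6)
  raw <- tr$extension_nm
  tr2 <- apply_smoothing(tr, 40)
  expect_identical(tr2$extension_nm, raw)
  expect_equal(tr2$extension_smooth_nm, boxcar_smooth(raw, 40))
})

test_that("the correlated-noise mode has the configured stationary spread", {
  cfg <- clamp_fixture_config(noise_model = "ou", ou_tau = 0.05)
  tr <- simulate_clamp(cfg, 8, 400, seed = 8)
  # stationary SD ~ 6 nm, successive samples correlated
  resid <- tr$extension_nm - ave(tr$extension_nm, tr$n_unfolded)
  expect_equal(sd(resid), 6, tolerance = 0.15)
  expect_gt(cor(head(resid, -1), tail(resid, -1)), 0.4)
})
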