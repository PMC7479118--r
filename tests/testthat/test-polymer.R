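test_that("thermal energy conversion is exact and guards absolute zero", {
  expect_equal(kBT_at_temperature(23), 0.0138065 * 296.15)
  expect_equal(kBT_at_temperature(23), 4.089, tolerance = 1e-3)
  expect_equal(kBT_at_temperature(37), 4.282, tolerance = 1e-3)
  expect_error(kBT_at_temperature(-273.15), "absolute zero")
  expect_error(kBT_at_temperature(-300), "absolute zero")
  e <- env_at(37)
  expect_s3_class(e, "mt_env")
  expect_equal(e$kBT, kBT_at_temperature(37))
})

test_that("worm-like-chain inversion reproduces the interpolation map", {
  expect_identical(wlc_relative_extension(0), 0)
  expect_gt(wlc_relative_extension(1e4), 0.99)
  expect_lt(wlc_relative_extension(1e4), 1)
  # exact inverse over the working range
  f_hat <- c(10^seq(-3, 3, length.out = 40), 0.654)
  x_hat <- wlc_relative_extension(f_hat)
  expect_equal(oracle_ms_map(x_hat), f_hat, tolerance = 1e-8)
  # agrees with an independent uniroot inversion
  expect_equal(x_hat, oracle_ms_inverse(f_hat), tolerance = 1e-9)
  # strictly increasing
  expect_true(all(diff(x_hat[order(f_hat)]) > 0))
  expect_error(wlc_relative_extension(-0.1), "non-negative")
})

test_that("peptide extension follows the WLC with per-residue contour", {
  env <- env_at(37)
  pep <- peptide_params(89)
  expect_equal(peptide_extension(0, pep, env), 0)
  want <- oracle_peptide_ext(3.5, 89, 0.8, env$kBT)
  expect_equal(peptide_extension(3.5, pep, env), want, tolerance = 1e-9)
  expect_equal(want, 11.6, tolerance = 0.03)   # ~11.4-11.6 nm at 3.5 pN
  f <- seq(0.1, 60, by = 0.1)
  ext <- peptide_extension(f, pep, env)
  expect_true(all(diff(ext) > 0))
  expect_true(all(ext < 89 * 0.38))
  expect_true(all(ext >= 0))
  expect_error(peptide_extension(-1, pep, env), "non-negative")
})

test_that("folded rod extension is the Langevin orientational average", {
  env <- env_at(37)
  rod <- folded_domain_params(4.4)
  expect_equal(folded_extension(0, rod, env), 0)
  expect_equal(folded_extension(1e6, rod, env), 4.4, tolerance = 1e-4)
  a <- 3.5 * 4.4 / env$kBT
  expect_equal(folded_extension(3.5, rod, env),
               4.4 * (1 / tanh(a) - 1 / a))
  expect_equal(folded_extension(3.5, rod, env), 3.18, tolerance = 1e-2)
  # small-force limit d*a/3 is continuous with the full expression
  expect_equal(folded_extension(1e-6, rod, env),
               4.4 * (1e-6 * 4.4 / env$kBT) / 3, tolerance = 1e-6)
})

test_that("handle extension uses the extensible WLC above its validity floor", {
  env <- env_at(23)
  h <- handle_params()
  Lc <- 572 * 0.338
  want <- Lc * (1 - 0.5 * sqrt(env$kBT / (10 * 45)) + 10 / 1200)
  expect_equal(handle_extension(10, h, env), want)
  f <- seq(0.6, 60, by = 0.2)
  expect_true(all(diff(handle_extension(f, h, env)) > 0))
  expect_error(handle_extension(0.3, h, env), "0.5 pN")
  expect_error(handle_extension(0, h, env), "0.5 pN")
})

test_that("construct-state extension is additive over elements", {
  env <- env_at(23)
  expect_equal(state_extension(construct_state(), 5, env), 0)
  pep <- peptide_params(100)
  single <- construct_state(list(pep))
  expect_equal(state_extension(single, 5, env),
               peptide_extension(5, pep, env))
  both <- construct_state(list(pep, folded_domain_params(4)))
  expect_equal(state_extension(both, 5, env),
               peptide_extension(5, pep, env) +
                 folded_extension(5, folded_domain_params(4), env))
})

test_that("looped/unlooped extension difference matches the published ~70 nm", {
  env <- env_at(23)
  st <- looping_construct_states()
  d <- state_extension(st$unlooped, 9.6, env) -
       state_extension(st$looped, 9.6, env)
  expect_equal(d, 70, tolerance = 10 / 70)
})

test_that("predicted unfolding step sizes match the published distributions", {
  env <- env_at(23)
  expect_equal(step_size_curve(tandem_state(0), tandem_state(0),
                               c(2, 5, 9), env)$step_nm, c(0, 0, 0))
  i27_step <- step_size_curve(tandem_state(0), tandem_state(1), 8, env)$step_nm
  expect_equal(i27_step, 14.9, tolerance = 1.5 / 14.9)
  sr <- sr4_domain()
  sr_step <- step_size_curve(tandem_state(0, N = 6, domain = sr),
                             tandem_state(1, N = 6, domain = sr),
                             7.9, env)$step_nm
  expect_equal(sr_step, 17.9, tolerance = 2 / 17.9)
})

test_that("conformational free energy matches a dense trapezoid oracle", {
  env <- env_at(37)
  i27 <- i27_domain()
  expect_equal(conformational_free_energy(0, i27$unfolded, i27$folded, env), 0)
  set.seed(42)
  for (i in 1:20) {
    n_res <- sample(50:250, 1)
    d <- runif(1, 2, 8)
    Fmax <- runif(1, 1, 12)
    temp <- runif(1, 15, 45)
    e <- env_at(temp)
    got <- conformational_free_energy(Fmax, peptide_params(n_res),
                                      folded_domain_params(d), e)
    want <- oracle_dphi_trapezoid(Fmax, n_res, d, e$kBT)
    expect_equal(got, want, tolerance = 1e-3 / max(abs(want), 1))
  }
})

test_that("free-energy integral is additive over force intervals", {
  env <- env_at(23)
  i27 <- i27_domain()
  phi <- function(F) conformational_free_energy(F, i27$unfolded, i27$folded, env)
  expect_equal(phi(2) + (phi(6) - phi(2)), phi(6), tolerance = 1e-8)
  # monotone non-decreasing where the unfolded chain is longer than the rod
  fs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(phi(fs)) >= 0))
})

test_that("free-energy force uncertainty matches a finite-difference check", {
  env <- env_at(37)
  i27 <- i27_domain()
  se <- dphi_standard_error(3.5, i27$unfolded, i27$folded, env)
  fd <- (conformational_free_energy(3.5 * 1.1, i27$unfolded, i27$folded, env) -
         conformational_free_energy(3.5 * 0.9, i27$unfolded, i27$folded, env)) / 2
  expect_equal(se, fd, tolerance = 0.02)
})
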