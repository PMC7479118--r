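# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the interpolation map is inverted with uniroot,
# integrals use a dense trapezoid rule, and closed forms are written out.

# forward Marko-Siggia interpolation map
oracle_ms_map <- function(x) x + 1 / (4 * (1 - x)^2) - 0.25

# invert the map by uniroot (independent of the package's bisection)
oracle_ms_inverse <- function(f_hat) {
  vapply(f_hat, function(f) {
    if (f == 0) return(0)
    uniroot(function(x) oracle_ms_map(x) - f, c(0, 1 - 1e-12),
            tol = 1e-12)$root
  }, numeric(1))
}

# peptide WLC extension via the uniroot inversion
oracle_peptide_ext <- function(force, n_res, lp, kBT, lc_per_res = 0.38) {
  n_res * lc_per_res * oracle_ms_inverse(force * lp / kBT)
}

# Langevin-averaged rod extension
oracle_rod_ext <- function(force, d, kBT) {
  a <- force * d / kBT
  ifelse(a < 1e-8, d * a / 3, d * (1 / tanh(a) - 1 / a))
}

# dense trapezoid for the conformational free-energy integral, in kBT
oracle_dphi_trapezoid <- function(F, n_res, d, kBT, lp = 0.8,
                                  n_points = 1e4) {
  f <- seq(0, F, length.out = n_points)
  y <- oracle_peptide_ext(f, n_res, lp, kBT) - oracle_rod_ext(f, d, kBT)
  sum((y[-1] + y[-n_points]) / 2 * diff(f)) / kBT
}

# analytic rupture-force CDF for a Bell law under a linear ramp from f0
oracle_rupture_cdf <- function(q, k0, dx, kBT, rate, f0 = 0) {
  b <- dx / kBT
  1 - exp(-k0 / (rate * b) * (exp(b * pmax(q, f0)) - exp(b * f0)))
}

# kernel-density mode of a sample; a fixed bandwidth shared across
# samples makes the kernel bias cancel when modes are compared
sample_mode <- function(x, bw = "nrd0") {
  d <- density(x, bw = bw, n = 4096, na.rm = TRUE)
  d$x[which.max(d$y)]
}

# greedy 1-1 matching of detected to true event times within a tolerance;
# returns c(tp, fp, fn)
match_events <- function(true_times, det_times, tol = 1) {
  used <- rep(FALSE, length(det_times))
  tp <- 0L; fn <- 0L
  for (te in true_times) {
    j <- which(!used & abs(det_times - te) < tol)
    if (length(j)) {
      used[j[which.min(abs(det_times[j] - te))]] <- TRUE
      tp <- tp + 1L
    } else fn <- fn + 1L
  }
  c(tp = tp, fp = sum(!used), fn = fn)
}
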