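# Force-dependent transition kinetics: Bell-Arrhenius rates, rupture-force
# distributions under constant loading rate, lifetime statistics, looping
# kinetics and rupture-force mixtures.

#' Bell rate-law parameters
#'
#' Zero-force rate and transition distance of one force-dependent
#' transition, \eqn{k(F) = k_0 \exp(F \Delta x / k_B T)}. A positive
#' `delta_x` means the transition is accelerated by force (rupture,
#' unfolding); a negative `delta_x` decelerated (looping, refolding).
#'
#' @param k0 Zero-force rate, 1/s, > 0.
#' @param delta_x Signed transition distance, nm.
#' @param k0_se,delta_x_se Optional standard errors.
#' @return Object of class `"rate_params"`.
#' @export
rate_params <- function(k0, delta_x, k0_se = NA_real_, delta_x_se = NA_real_) {
  stopifnot(k0 > 0)
  structure(list(k0 = k0, delta_x = delta_x,
                 k0_se = k0_se, delta_x_se = delta_x_se),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("<rate_params> k0 = %.4g 1/s, delta_x = %.3f nm\n",
              x$k0, x$delta_x))
  invisible(x)
}

#' Bell-Arrhenius force-dependent rate
#'
#' @param force Force in pN, >= 0. Vectorised.
#' @param params A [rate_params()] object.
#' @param env An [env_at()] environment.
#' @return Rate in 1/s.
#' @export
bell_rate <- function(force, params, env) {
  stopifnot(inherits(params, "rate_params"), inherits(env, "mt_env"))
  if (any(force < 0)) stop("force must be non-negative")
  params$k0 * exp(force * params$delta_x / env$kBT)
}

#' Fit the Bell rate law to (force, rate) data
#'
#' Least-squares line through \eqn{(F, \ln k)}: the intercept gives
#' \eqn{k_0}, the slope times \eqn{k_B T} the transition distance. With
#' exactly two points this is the closed-form two-point solution.
#'
#' @param forces Forces in pN (>= 2 distinct values).
#' @param rates Rates in 1/s, all > 0.
#' @param env An [env_at()] environment.
#' @return A [rate_params()] with standard errors (NA for n = 2).
#' @export
fit_bell <- function(forces, rates, env) {
  stopifnot(inherits(env, "mt_env"))
  if (length(forces) != length(rates) || length(unique(forces)) < 2)
    stop("need rates at >= 2 distinct forces")
  if (any(rates <= 0)) stop("all rates must be positive")
  fit <- lm(log(rates) ~ forces)
  co <- coef(fit)
  se <- if (length(forces) > 2)
    suppressWarnings(sqrt(diag(vcov(fit)))) else c(NA_real_, NA_real_)
  rate_params(k0 = exp(co[[1]]),
              delta_x = co[[2]] * env$kBT,
              k0_se = exp(co[[1]]) * se[[1]],
              delta_x_se = se[[2]] * env$kBT)
}

#' Constant-loading-rate protocol
#'
#' @param rate Loading rate in pN/s, > 0.
#' @param f_start,f_end Force window in pN, `f_end > f_start`.
#' @return Object of class `"loading_protocol"`.
#' @export
loading_protocol <- function(rate, f_start = 0, f_end = Inf) {
  stopifnot(rate > 0, f_end > f_start, f_start >= 0)
  structure(list(rate = rate, f_start = f_start, f_end = f_end),
            class = "loading_protocol")
}

# Integrated Bell hazard between f0 and f at loading rate r:
# (1/r) * int_f0^f k0 exp(x dx/kBT) dx  (closed form)
.bell_hazard_integral <- function(f, f0, params, env, rate) {
  b <- params$delta_x / env$kBT
  params$k0 / (rate * b) * (exp(b * f) - exp(b * f0))
}

#' Rupture-force density under a linear force ramp
#'
#' First-passage density of a single Bell transition under a constant
#' loading rate r, starting from the looped/folded state at `f_start`:
#' \deqn{p(F) = \frac{k(F)}{r}\exp\!\left(-\frac1r \int_{F_0}^{F} k(f)\,
#' df\right)} with the closed-form Bell integral. Requires `delta_x > 0`
#' (force-accelerated rupture branch).
#'
#' @param force Force(s) at which to evaluate the density, pN.
#' @param protocol A [loading_protocol()].
#' @param params A [rate_params()] with positive `delta_x`.
#' @param env An [env_at()] environment.
#' @return Density values (1/pN); integrates to 1 over `[f_start, Inf)`.
#' @export
rupture_force_pdf <- function(force, protocol, params, env) {
  stopifnot(inherits(protocol, "loading_protocol"))
  if (params$delta_x <= 0)
    stop("rupture-force density requires delta_x > 0")
  # work in logs: the hazard integral overflows double precision long
  # after the density has decayed to zero
  logk <- log(params$k0) + pmax(force, 0) * params$delta_x / env$kBT
  H <- .bell_hazard_integral(force, protocol$f_start, params, env,
                             protocol$rate)
  out <- exp(logk - log(protocol$rate) - H)
  out[!is.finite(H)] <- 0
  out[force < protocol$f_start] <- 0
  out
}

#' Most probable rupture force under a linear ramp
#'
#' Closed form (for a ramp from zero force):
#' \eqn{F^* = (k_B T/\Delta x)\,\ln\!\big(r \Delta x / (k_0 k_B T)\big)},
#' valid when the logarithm's argument exceeds 1; otherwise the density is
#' monotone decreasing and the mode is at the start of the ramp.
#'
#' @inheritParams rupture_force_pdf
#' @return Modal rupture force in pN.
#' @export
modal_rupture_force <- function(protocol, params, env) {
  if (params$delta_x <= 0) stop("requires delta_x > 0")
  arg <- protocol$rate * params$delta_x / (params$k0 * env$kBT)
  if (arg <= 1) return(protocol$f_start)
  max(env$kBT / params$delta_x * log(arg), protocol$f_start)
}

# Doane's rule for histogram bin count
.doane_bins <- function(x) {
  n <- length(x)
  g1 <- mean((x - mean(x))^3) / (sd(x) * sqrt((n - 1) / n))^3
  sg1 <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  max(3L, ceiling(1 + log2(n) + log2(1 + abs(g1) / sg1)))
}

#' Fit a single-exponential lifetime to dwell times
#'
#' Default estimator is the maximum-likelihood one (the sample mean, which
#' is unbiased and binning-free). The histogram mode reproduces the
#' common practice of least-squares fitting the binned dwell histogram to
#' \eqn{A e^{-t/\tau}} (Doane-rule binning) and is provided as a
#' cross-check. The standard error is \eqn{\tau/\sqrt{n - 1}}.
#'
#' @param dwells Dwell times in s, all > 0, length >= 2.
#' @param method `"mle"` (default) or `"histogram"`.
#' @return Object of class `"dwell_fit"`: list with `tau`, `se`, `n`,
#'   `method` and the input `dwells`.
#' @export
fit_exponential_lifetime <- function(dwells, method = c("mle", "histogram")) {
  method <- match.arg(method)
  n <- length(dwells)
  if (n < 2) stop("need at least two dwell times")
  if (any(dwells <= 0)) stop("dwell times must be positive")
  tau <- if (method == "mle") {
    mean(dwells)
  } else {
    h <- graphics::hist(dwells, breaks = .doane_bins(dwells), plot = FALSE)
    t_mid <- h$mids
    cts <- h$counts
    if (length(unique(t_mid)) < 2 || sum(cts > 0) < 2) {
      mean(dwells)   # degenerate histogram: fall back to the MLE
    } else {
      start <- list(A = max(cts), tau = mean(dwells))
      # Poisson count noise: inverse-variance weights 1/max(c, 1)
      fit <- minpack.lm::nlsLM(cts ~ A * exp(-t_mid / tau), start = start,
                               weights = 1 / pmax(cts, 1),
                               lower = c(1e-12, 1e-12),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      coef(fit)[["tau"]]
    }
  }
  structure(list(tau = tau, se = tau / sqrt(n - 1), n = n,
                 method = method, dwells = dwells),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> tau = %.4g +/- %.2g s (n = %d, %s)\n",
              x$tau, x$se, x$n, x$method))
  invisible(x)
}

#' Two-state looping/unlooping rates
#'
#' @param k_p Looping (formation) rate, 1/s, >= 0.
#' @param k_u Unlooping (rupture) rate, 1/s, >= 0. Not both zero.
#' @param k_p_se,k_u_se Optional standard errors.
#' @return Object of class `"two_state_rates"`.
#' @export
two_state_rates <- function(k_p, k_u, k_p_se = NA_real_, k_u_se = NA_real_) {
  stopifnot(k_p >= 0, k_u >= 0, k_p + k_u > 0)
  structure(list(k_p = k_p, k_u = k_u, k_p_se = k_p_se, k_u_se = k_u_se),
            class = "two_state_rates")
}

#' Looping probability after a waiting time
#'
#' Probability that a construct starting unlooped is looped after waiting
#' `delta_t` at constant force:
#' \deqn{P(\Delta t) = \frac{k_p}{k_p + k_u}\left(1 -
#'   e^{-(k_p + k_u)\Delta t}\right).}
#'
#' @param delta_t Waiting time in s, >= 0. Vectorised.
#' @param rates A [two_state_rates()] object.
#' @return Probability in `[0, k_p/(k_p+k_u)]`.
#' @export
looping_probability <- function(delta_t, rates) {
  stopifnot(inherits(rates, "two_state_rates"))
  if (any(delta_t < 0)) stop("delta_t must be non-negative")
  ktot <- rates$k_p + rates$k_u
  rates$k_p / ktot * (1 - exp(-ktot * delta_t))
}

#' Fit the two-state looping model to measured looping probabilities
#'
#' Weighted nonlinear least squares of
#' \eqn{P(\Delta t) = \frac{k_p}{k_p+k_u}(1 - e^{-(k_p+k_u)\Delta t})}.
#' When cycle counts are given, weights are the inverse binomial variances
#' \eqn{n/\max(P(1-P), \epsilon)}; otherwise the fit is unweighted.
#' The fit is flagged ill-conditioned when no time point reaches beyond
#' one relaxation time \eqn{1/(k_p + k_u)} (the plateau, and hence
#' \eqn{k_u}, is then unidentified).
#'
#' @param delta_t Waiting times in s (>= 3 points).
#' @param probability Measured looping probabilities.
#' @param n_cycles Cycles per point (scalar or vector), for weighting.
#' @return Object of class `"looping_fit"`: the fitted
#'   [two_state_rates()] with asymptotic standard errors, plateau, and an
#'   `ill_conditioned` flag.
#' @export
fit_looping <- function(delta_t, probability, n_cycles = NULL) {
  if (length(delta_t) < 3) stop("need >= 3 time points")
  if (length(probability) != length(delta_t))
    stop("delta_t and probability lengths differ")
  if (all(probability == 0)) stop("all-zero probabilities: nothing to fit")
  w <- if (is.null(n_cycles)) rep(1, length(delta_t))
       else n_cycles / pmax(probability * (1 - probability), 1e-4)
  dt <- delta_t; P <- probability
  # profile the weighted least squares over the total rate: for fixed
  # k_tot the plateau A enters linearly, so the inner problem is closed
  # form and the outer problem is a robust 1-D minimisation
  profile_A <- function(ktot) {
    g <- 1 - exp(-ktot * dt)
    min(max(sum(w * g * P) / sum(w * g^2), 1e-10), 1)
  }
  obj <- function(log_ktot) {
    ktot <- exp(log_ktot)
    A <- profile_A(ktot)
    sum(w * (P - A * (1 - exp(-ktot * dt)))^2)
  }
  grid <- seq(log(0.01 / max(dt)), log(100 / min(dt[dt > 0])),
              length.out = 200)
  o0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
  opt <- optimize(obj, o0 + c(-1, 1), tol = 1e-10)
  ktot <- exp(opt$minimum)
  A <- profile_A(ktot)
  k_p <- A * ktot
  k_u <- max((1 - A) * ktot, 1e-10)
  # polish with the full 2-parameter fit to obtain asymptotic errors
  se <- c(NA_real_, NA_real_)
  fit <- tryCatch({
    nls_fit <- minpack.lm::nlsLM(
      P ~ k_p / (k_p + k_u) * (1 - exp(-(k_p + k_u) * dt)),
      start = list(k_p = k_p, k_u = k_u), weights = w,
      lower = c(1e-10, 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- coef(nls_fit)
    k_p <- co[["k_p"]]; k_u <- co[["k_u"]]
    se <- tryCatch(suppressWarnings(sqrt(diag(vcov(nls_fit)))),
                   error = function(e) c(NA_real_, NA_real_))
    nls_fit
  }, error = function(e) NULL)
  ktot <- k_p + k_u
  structure(list(
    rates = two_state_rates(k_p, k_u, se[[1]], se[[2]]),
    plateau = k_p / ktot,
    ill_conditioned = max(delta_t) < 1 / ktot,
    fit = fit), class = "looping_fit")
}

#' @export
print.looping_fit <- function(x, ...) {
  cat(sprintf("<looping_fit> k_p = %.4g, k_u = %.4g 1/s (plateau %.3f)%s\n",
              x$rates$k_p, x$rates$k_u, x$plateau,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

# One EM pass for a 1-D two-component Gaussian mixture.
.em_gauss2 <- function(x, max_iter, tol) {
  q <- quantile(x, c(0.3, 0.7), names = FALSE)
  mu <- q
  s <- rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(r); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s <- sqrt(pmax(c(sum(r * (x - mu[1])^2) / n1,
                     sum((1 - r) * (x - mu[2])^2) / n2), 1e-12))
  }
  list(mu = mu, sd = s, w = w, loglik = ll_old, converged = converged)
}

#' Gaussian mixture decomposition of rupture forces
#'
#' Fits a one- or two-component Gaussian mixture to a rupture-force sample
#' by expectation-maximisation with deterministic moment-based
#' initialisation (component means started at the 30th/70th percentiles).
#' The component with the higher mean is labelled "strong". The weight of
#' the strong component gets a bootstrap standard error.
#'
#' @param rupture_forces Rupture forces in pN.
#' @param n_components 1 or 2.
#' @param n_boot Bootstrap resamples for the weight standard error.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `"rupture_mixture"`: `weight_strong` (with
#'   `weight_strong_se`), per-component `strong`/`weak` mean and sd, and a
#'   `converged` flag.
#' @export
fit_rupture_mixture <- function(rupture_forces, n_components = 2,
                                n_boot = 200, max_iter = 500, tol = 1e-8,
                                seed = NULL) {
  stopifnot(n_components %in% c(1, 2))
  x <- as.numeric(rupture_forces)
  if (n_components == 1) {
    return(structure(list(
      weight_strong = 1, weight_strong_se = 0,
      strong = c(mean = mean(x), sd = sd(x)),
      weak = c(mean = NA_real_, sd = NA_real_),
      converged = TRUE, loglik = sum(dnorm(x, mean(x), sd(x), log = TRUE))),
      class = "rupture_mixture"))
  }
  if (length(x) < 20) stop("need >= 20 rupture forces for a 2-component fit")
  em_strong <- function(xx) {
    fit <- .em_gauss2(xx, max_iter, tol)
    st <- which.max(fit$mu)
    list(fit = fit, strong = st)
  }
  base <- em_strong(x)
  st <- base$strong; wk <- 3 - st
  w_boot <- if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n_boot), function(i) {
      b <- em_strong(sample(x, replace = TRUE))
      b$fit$w[b$strong]
    }, numeric(1))
  } else NA_real_
  structure(list(
    weight_strong = base$fit$w[st],
    weight_strong_se = if (n_boot > 0) sd(w_boot) else NA_real_,
    strong = c(mean = base$fit$mu[st], sd = base$fit$sd[st]),
    weak = c(mean = base$fit$mu[wk], sd = base$fit$sd[wk]),
    converged = base$fit$converged, loglik = base$fit$loglik),
    class = "rupture_mixture")
}

#' @export
print.rupture_mixture <- function(x, ...) {
  cat(sprintf(
    "<rupture_mixture> strong: %.2f +/- %.2f pN (w = %.3f +/- %.3f); weak: %.2f +/- %.2f pN\n",
    x$strong[["mean"]], x$strong[["sd"]], x$weight_strong,
    x$weight_strong_se, x$weak[["mean"]], x$weak[["sd"]]))
  invisible(x)
}
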