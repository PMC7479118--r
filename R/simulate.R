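# Synthetic bead-height trajectory generator: continuous-time Markov
# dynamics of two-state mechanical units under force clamp, linear force
# ramp, and repeated force-jump looping cycles, with additive bead noise
# and known ground truth recorded in an event log.

#' A two-state mechanical unit
#'
#' One independently switching element of a simulated construct: a folded
#' domain (rigid rod) that converts into an unfolded peptide and, if a
#' refolding law is given, back. The looped/unlooped complex is the same
#' object with the looped bundle as the "folded" side and the released
#' linker chain as the "unfolded" side.
#'
#' @param label Unit label used in event logs.
#' @param folded [folded_domain_params()] of the folded/looped side.
#' @param unfolded [peptide_params()] of the unfolded/released side.
#' @param unfold [rate_params()] of the forward (force-accelerated)
#'   transition.
#' @param refold Optional [rate_params()] of the reverse transition;
#'   `NULL` makes unfolding irreversible.
#' @param state0 Initial state, `"folded"` or `"unfolded"`.
#' @return Object of class `"two_state_unit"`.
#' @export
two_state_unit <- function(label, folded, unfolded, unfold, refold = NULL,
                           state0 = c("folded", "unfolded")) {
  state0 <- match.arg(state0)
  stopifnot(inherits(folded, "folded_domain_params"),
            inherits(unfolded, "peptide_params"),
            inherits(unfold, "rate_params"),
            is.null(refold) || inherits(refold, "rate_params"))
  structure(list(label = label, folded = folded, unfolded = unfolded,
                 unfold = unfold, refold = refold, state0 = state0),
            class = "two_state_unit")
}

#' Simulation configuration
#'
#' Bundles the construct (a list of [two_state_unit()]s plus passive
#' elements), the environment, and the acquisition model: sampling rate,
#' additive bead-noise SD on the raw channel, the noise model (white
#' Gaussian by default, or an Ornstein-Uhlenbeck correlated mode), and the
#' boxcar smoothing window applied to produce the smoothed channel.
#'
#' @param units List of [two_state_unit()]s.
#' @param handle A [handle_params()] or `NULL` for no handle.
#' @param extra List of additional passive elements (peptide or folded
#'   domain params) whose extension adds to every state.
#' @param env An [env_at()] environment.
#' @param sampling_rate Samples per second, > 0.
#' @param noise_sd Raw bead-noise SD in nm, >= 0. The default 6 nm is
#'   calibrated so that 20-point smoothing leaves ~1.3 nm of jitter.
#' @param noise_model `"white"` or `"ou"`.
#' @param ou_tau Correlation time of the OU mode, s.
#' @param smoothing_window Boxcar window (samples) for the smoothed channel.
#' @param seed Default seed recorded in outputs; per-call seeds override.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(units, handle = handle_params(), extra = list(),
                       env = env_at(23), sampling_rate = 50, noise_sd = 6,
                       noise_model = c("white", "ou"), ou_tau = 0.05,
                       smoothing_window = 20, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(units) >= 1, sampling_rate > 0, noise_sd >= 0,
            smoothing_window >= 1, inherits(env, "mt_env"))
  ok <- vapply(units, inherits, logical(1), what = "two_state_unit")
  if (!all(ok)) stop("units must be two_state_unit objects")
  structure(list(units = units, handle = handle, extra = extra, env = env,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 noise_model = noise_model, ou_tau = ou_tau,
                 smoothing_window = smoothing_window, seed = seed),
            class = "sim_config")
}

# extension of the passive (state-independent) part of the construct
.base_extension <- function(config, force) {
  out <- if (is.null(config$handle)) rep(0, length(force))
         else handle_extension(force, config$handle, config$env)
  for (e in config$extra)
    out <- out + element_extension(e, force, config$env)
  out
}

# per-unit folded and unfolded extensions at force (vectorised over force)
.unit_extensions <- function(unit, force, env) {
  list(folded = folded_extension(force, unit$folded, env),
       unfolded = peptide_extension(force, unit$unfolded, env))
}

.make_noise <- function(n, config) {
  if (config$noise_sd == 0) return(numeric(n))
  if (config$noise_model == "white") {
    rnorm(n, 0, config$noise_sd)
  } else {
    dt <- 1 / config$sampling_rate
    a <- exp(-dt / config$ou_tau)
    innov <- rnorm(n, 0, config$noise_sd * sqrt(1 - a^2))
    innov[1] <- rnorm(1, 0, config$noise_sd)
    as.numeric(stats::filter(innov, a, method = "recursive"))
  }
}

#' Boxcar smoothing with partial edge windows
#'
#' Centred moving average of width `window`; the edges use the largest
#' symmetric window available. `window = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param window Window width in samples, >= 1, <= `length(x)`.
#' @return Smoothed vector of the same length.
#' @export
boxcar_smooth <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window exceeds trace length")
  if (window == 1) return(x)
  h1 <- floor((window - 1) / 2)
  h2 <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h1, 1)
  hi <- pmin(i + h2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.finish_trajectory <- function(time, force, clean, state, config, events,
                               seed, protocol = NULL) {
  raw <- clean + .make_noise(length(time), config)
  smooth <- boxcar_smooth(raw, min(config$smoothing_window, length(raw)))
  traj <- data.frame(time_s = time, force_pN = force, extension_nm = raw,
                     extension_smooth_nm = smooth, n_unfolded = state)
  attr(traj, "events") <- events
  attr(traj, "seed") <- seed
  attr(traj, "config") <- config
  attr(traj, "protocol") <- protocol
  class(traj) <- c("mt_trajectory", "data.frame")
  traj
}

.empty_events <- function() {
  data.frame(time_s = numeric(0), unit = character(0),
             direction = character(0), force_pN = numeric(0),
             step_nm = numeric(0))
}

#' Simulate a force-clamp trajectory
#'
#' Exact-waiting-time (Gillespie) simulation of the construct's two-state
#' units at constant force. Transition rates are Bell rates evaluated at
#' the clamp force; each event's step size in the event log is the exact
#' model extension change (noise applies to samples only).
#'
#' @param config A [sim_config()].
#' @param force Clamp force, pN.
#' @param duration Trace length, s, > 0.
#' @param seed Seed (default from config). Identical (config, seed) pairs
#'   give bit-identical trajectories.
#' @return An `"mt_trajectory"` data frame (`time_s`, `force_pN`,
#'   `extension_nm` raw, `extension_smooth_nm`, `n_unfolded`) with the
#'   ground-truth event log in `attr(, "events")`.
#' @export
simulate_clamp <- function(config, force, duration, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), duration > 0)
  set.seed(seed)
  env <- config$env
  nu <- length(config$units)
  kf <- numeric(nu); kr <- numeric(nu); dstep <- numeric(nu)
  unfolded <- logical(nu)
  for (i in seq_len(nu)) {
    u <- config$units[[i]]
    kf[i] <- bell_rate(force, u$unfold, env)
    kr[i] <- if (is.null(u$refold)) 0 else bell_rate(force, u$refold, env)
    ex <- .unit_extensions(u, force, env)
    dstep[i] <- ex$unfolded - ex$folded
    unfolded[i] <- u$state0 == "unfolded"
  }
  if (sum(ifelse(unfolded, kr, kf)) == 0)
    warning("no transition is possible from the initial state: constant-state trace")
  ev_t <- numeric(0); ev_i <- integer(0); ev_dir <- character(0)
  t <- 0
  repeat {
    active <- ifelse(unfolded, kr, kf)
    R <- sum(active)
    if (R == 0) break
    t <- t + rexp(1, R)
    if (t > duration) break
    i <- sample.int(nu, 1, prob = active)
    unfolded[i] <- !unfolded[i]
    ev_t <- c(ev_t, t); ev_i <- c(ev_i, i)
    ev_dir <- c(ev_dir, if (unfolded[i]) "unfold" else "refold")
  }
  events <- if (length(ev_t)) {
    data.frame(time_s = ev_t,
               unit = vapply(config$units[ev_i], `[[`, "", "label"),
               direction = ev_dir, force_pN = force,
               step_nm = ifelse(ev_dir == "unfold", dstep[ev_i],
                                -dstep[ev_i]))
  } else .empty_events()
  time <- seq(0, duration, by = 1 / config$sampling_rate)
  # reconstruct the per-sample occupancy from the event sequence
  state0 <- vapply(config$units, function(u) u$state0 == "unfolded",
                   logical(1))
  base <- .base_extension(config, force)
  exts_f <- vapply(seq_len(nu), function(i)
    .unit_extensions(config$units[[i]], force, env)$folded, numeric(1))
  exts_u <- exts_f + dstep
  seg_state <- matrix(rep(state0, length(ev_t) + 1), ncol = nu, byrow = TRUE)
  if (length(ev_t))
    for (k in seq_along(ev_t))
      seg_state[(k + 1):nrow(seg_state), ev_i[k]] <-
        !seg_state[k, ev_i[k]]
  seg_ext <- base + apply(seg_state, 1, function(s)
    sum(ifelse(s, exts_u, exts_f)))
  seg_n <- rowSums(seg_state)
  idx <- findInterval(time, ev_t) + 1
  .finish_trajectory(time, rep(force, length(time)), seg_ext[idx],
                     seg_n[idx], config, events, seed)
}

#' Sample rupture forces from the Bell first-passage distribution
#'
#' Exact sampler by inversion of the integrated hazard (closed form for
#' the Bell rate law) under a linear force ramp. Forces beyond
#' `protocol$f_end` are censored and returned as `NA`.
#'
#' @param n Number of samples.
#' @param protocol A [loading_protocol()].
#' @param params A [rate_params()] with positive `delta_x`.
#' @param env An [env_at()] environment.
#' @param seed Optional seed.
#' @return Numeric vector of rupture forces in pN (`NA` = censored).
#' @export
sample_rupture_forces <- function(n, protocol, params, env, seed = NULL) {
  if (params$delta_x <= 0) stop("requires delta_x > 0")
  if (!is.null(seed)) set.seed(seed)
  b <- params$delta_x / env$kBT
  u <- rexp(n)
  f <- log(exp(b * protocol$f_start) +
             u * protocol$rate * b / params$k0) / b
  f[f > protocol$f_end] <- NA_real_
  f
}

#' Simulate a constant-loading-rate ramp
#'
#' Each folded unit's rupture force is drawn exactly by inverse integrated
#' hazard of its Bell law; refolding is neglected during the ramp (reverse
#' rates fall with force). The bead-height trace follows the force-
#' dependent state extension with additive noise.
#'
#' @param config A [sim_config()].
#' @param protocol A [loading_protocol()] with finite `f_end` and
#'   `f_start >= 0.5` pN when a handle is present.
#' @param seed Seed (default from config).
#' @param rupture_unit Label of the unit whose first passage is reported
#'   as "the" rupture force; default is the unit with the largest
#'   extension change at `f_end`.
#' @return List of class `"ramp_result"`: `trajectory`, `rupture_force`
#'   (pN, `NA` if censored), `censored`, `events`.
#' @export
simulate_ramp <- function(config, protocol, seed = config$seed,
                          rupture_unit = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(protocol, "loading_protocol"),
            is.finite(protocol$f_end))
  set.seed(seed)
  env <- config$env
  nu <- length(config$units)
  f_rup <- vapply(seq_len(nu), function(i) {
    u <- config$units[[i]]
    if (u$state0 == "unfolded") return(-Inf)   # already unfolded
    if (u$unfold$delta_x <= 0) return(Inf)
    b <- u$unfold$delta_x / env$kBT
    log(exp(b * protocol$f_start) +
          rexp(1) * protocol$rate * b / u$unfold$k0) / b
  }, numeric(1))
  t_end <- (protocol$f_end - protocol$f_start) / protocol$rate
  time <- seq(0, t_end, by = 1 / config$sampling_rate)
  force <- protocol$f_start + protocol$rate * time
  base <- .base_extension(config, force)
  clean <- base
  n_unf <- integer(length(time))
  for (i in seq_len(nu)) {
    u <- config$units[[i]]
    ex <- .unit_extensions(u, force, env)
    unf <- force >= f_rup[i]
    clean <- clean + ifelse(unf, ex$unfolded, ex$folded)
    n_unf <- n_unf + unf
  }
  obs <- which(is.finite(f_rup) & f_rup > 0 & f_rup <= protocol$f_end)
  events <- if (length(obs)) {
    ord <- obs[order(f_rup[obs])]
    data.frame(
      time_s = (f_rup[ord] - protocol$f_start) / protocol$rate,
      unit = vapply(config$units[ord], `[[`, "", "label"),
      direction = "unfold", force_pN = f_rup[ord],
      step_nm = vapply(ord, function(i) {
        ex <- .unit_extensions(config$units[[i]], f_rup[i], env)
        ex$unfolded - ex$folded
      }, numeric(1)))
  } else .empty_events()
  if (is.null(rupture_unit)) {
    dstep_end <- vapply(seq_len(nu), function(i) {
      ex <- .unit_extensions(config$units[[i]], protocol$f_end, env)
      ex$unfolded - ex$folded
    }, numeric(1))
    rupture_unit <- config$units[[which.max(dstep_end)]]$label
  }
  iu <- which(vapply(config$units, `[[`, "", "label") == rupture_unit)[1]
  censored <- !is.finite(f_rup[iu]) || f_rup[iu] > protocol$f_end
  traj <- .finish_trajectory(time, force, clean, n_unf, config, events,
                             seed, protocol = protocol)
  structure(list(trajectory = traj,
                 rupture_force = if (censored) NA_real_ else f_rup[iu],
                 censored = censored, events = events),
            class = "ramp_result")
}

#' Bell rates of the looping/unlooping pair at a hold force
#'
#' @param hold_force Force during the waiting period, pN.
#' @param loop [rate_params()] of the looping transition (negative
#'   `delta_x`: force-decelerated).
#' @param unloop [rate_params()] of the unlooping transition.
#' @param env An [env_at()] environment.
#' @return A [two_state_rates()] evaluated at `hold_force`.
#' @export
looping_rates_at <- function(hold_force, loop, unloop, env) {
  two_state_rates(bell_rate(hold_force, loop, env),
                  bell_rate(hold_force, unloop, env))
}

#' Simulate repeated force-jump looping cycles
#'
#' Each cycle starts in the unlooped state (prepared at high force),
#' evolves as a two-state continuous-time Markov chain with rates `k_p`
#' (loop) and `k_u` (unloop) during the waiting time `delta_t` at the hold
#' force, and reports the state found at the end of the wait (assessed at
#' the detection force, which does not alter the state).
#'
#' @param rates A [two_state_rates()] at the hold force (see
#'   [looping_rates_at()]).
#' @param delta_t Waiting time, s, >= 0.
#' @param n_cycles Number of cycles, >= 1.
#' @param seed Optional seed.
#' @return `data.frame` with `cycle`, `delta_t`, `looped` (logical).
#' @export
simulate_looping_cycles <- function(rates, delta_t, n_cycles, seed = NULL) {
  stopifnot(inherits(rates, "two_state_rates"), n_cycles >= 1, delta_t >= 0)
  if (!is.null(seed)) set.seed(seed)
  looped <- logical(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    state <- FALSE   # unlooped
    t <- 0
    repeat {
      r <- if (state) rates$k_u else rates$k_p
      if (r == 0) break
      t <- t + rexp(1, r)
      if (t > delta_t) break
      state <- !state
    }
    looped[cyc] <- state
  }
  data.frame(cycle = seq_len(n_cycles), delta_t = delta_t, looped = looped)
}

#' Re-smooth a trajectory
#'
#' Replaces the smoothed channel with a boxcar of the given window over
#' the preserved raw channel.
#'
#' @param trajectory An `"mt_trajectory"`.
#' @param window Window width in samples, >= 1; must not exceed the trace
#'   length.
#' @return The trajectory with an updated `extension_smooth_nm`.
#' @export
apply_smoothing <- function(trajectory, window) {
  stopifnot(inherits(trajectory, "mt_trajectory"))
  trajectory$extension_smooth_nm <-
    boxcar_smooth(trajectory$extension_nm, window)
  attr(trajectory, "smoothing_window") <- window
  trajectory
}
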