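# Trace analysis: recover step events, rupture forces, dwell times and
# bead-height occupancy histograms from (synthetic or real) trajectories.

# Robust noise SD of the raw channel from first differences.
.raw_noise_sd <- function(x) mad(diff(x)) / sqrt(2)

#' Detect step events in a bead-height trajectory
#'
#' Sliding two-sample mean-difference (Welch-type) detector: at every
#' sample the means of the `window` samples before and after are compared;
#' the statistic is the mean difference over its standard error under the
#' locally estimated raw noise. Candidate change points are contiguous
#' runs of super-threshold statistic, pruned by non-maximum suppression
#' (one event per run, at the maximum statistic; ties break toward the
#' earlier sample; events closer than one window keep the larger
#' statistic). Step sizes are estimated from flanking medians and events
#' smaller than `min_step` are discarded. Detection operates on the raw
#' channel with its own windowed averaging; times are reported on the raw
#' time base. Adding a constant offset to the extension channel does not
#' change the output.
#'
#' @param trajectory An `"mt_trajectory"` (or data frame with `time_s` and
#'   `extension_nm`).
#' @param min_step Minimum detectable step in nm; default is 3 times the
#'   estimated noise SD of the window-averaged channel.
#' @param window Half-comparison window in samples.
#' @param threshold Detection threshold on the Welch statistic.
#' @return `data.frame` of class `"step_events"`: `time_s`, `force_pN`,
#'   `size_nm` (signed), `statistic`.
#' @export
detect_steps <- function(trajectory, min_step = NULL, window = 25,
                         threshold = 5) {
  x <- trajectory$extension_nm
  n <- length(x)
  if (n <= 2 * window) stop("trace must be longer than 2 * window")
  sigma_raw <- .raw_noise_sd(x)
  if (is.null(min_step))
    min_step <- 3 * sigma_raw / sqrt(window)
  cs <- cumsum(c(0, x))
  i <- window:(n - window)          # change point between i and i + 1
  m_after <- (cs[i + window + 1] - cs[i + 1]) / window
  m_before <- (cs[i + 1] - cs[i - window + 1]) / window
  d <- m_after - m_before
  se <- max(sigma_raw, 1e-12) * sqrt(2 / window)
  stat <- abs(d) / se
  hits <- stat > threshold
  empty <- data.frame(time_s = numeric(0), force_pN = numeric(0),
                      size_nm = numeric(0), statistic = numeric(0))
  class(empty) <- c("step_events", "data.frame")
  if (!any(hits)) return(empty)
  # one candidate per contiguous run: maximum statistic, earlier sample on ties
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(stat[seg])])
  }
  # merge candidates closer than one window, keeping the larger statistic
  if (length(cand) > 1) {
    keep <- rep(TRUE, length(cand))
    ord <- order(stat[cand], decreasing = TRUE)
    taken <- integer(0)
    for (j in ord) {
      if (any(abs(cand[j] - taken) < window)) keep[j] <- FALSE
      else taken <- c(taken, cand[j])
    }
    cand <- sort(cand[keep])
  }
  idx <- i[cand]
  # signed sizes from flanking medians (small guard gap at the edge)
  gap <- max(1L, window %/% 5)
  size <- vapply(idx, function(j) {
    left <- x[max(1, j - window):max(1, j - gap)]
    right <- x[min(n, j + gap):min(n, j + window)]
    median(right) - median(left)
  }, numeric(1))
  ok <- abs(size) >= min_step
  out <- data.frame(time_s = trajectory$time_s[idx[ok]],
                    force_pN = trajectory$force_pN[idx[ok]],
                    size_nm = size[ok], statistic = stat[cand][ok])
  class(out) <- c("step_events", "data.frame")
  out
}

#' Extract rupture forces from a batch of ramp trajectories
#'
#' For each force-ramp cycle the rupture (unlooping) event is identified
#' as the largest detected step -- the release of the looped linker
#' dwarfs any domain unfolding -- and the force at that step is recorded.
#' Cycles with no detectable step are censored and only counted.
#'
#' @param trajectories List of `"mt_trajectory"` ramp traces (or of
#'   `"ramp_result"`s, whose trajectories are used).
#' @param min_step Minimum step size in nm; the default of 20 nm rejects
#'   both the smooth worm-like-chain drift a ramp imprints on the running
#'   means and any residual domain-unfolding steps, while the unlooping
#'   release itself is several times larger.
#' @param window,threshold Passed to [detect_steps()].
#' @return List with `forces` (pN, one per uncensored cycle) and
#'   `n_censored`.
#' @export
extract_rupture_forces <- function(trajectories, min_step = 20,
                                   window = 25, threshold = 5) {
  forces <- numeric(0)
  n_censored <- 0L
  for (tr in trajectories) {
    if (inherits(tr, "ramp_result")) tr <- tr$trajectory
    ev <- detect_steps(tr, min_step = min_step, window = window,
                       threshold = threshold)
    if (!nrow(ev)) { n_censored <- n_censored + 1L; next }
    forces <- c(forces, ev$force_pN[which.max(abs(ev$size_nm))])
  }
  if (!length(forces)) warning("no steps detected in any trajectory")
  list(forces = forces, n_censored = n_censored)
}

#' Dwell times between detected events
#'
#' Durations from the force arrival (trace start, or `t0`) or the previous
#' event to each event, labelled by transition direction from the sign of
#' the step.
#'
#' @param trajectory An `"mt_trajectory"`.
#' @param events A `"step_events"` data frame, sorted in time.
#' @param t0 Reference start time (default: first sample).
#' @return `data.frame` with `dwell_s` and `direction` (`"up"` for
#'   extension increase, `"down"` for decrease); zero rows when no events
#'   (censoring is the caller's record).
#' @export
extract_dwell_times <- function(trajectory, events, t0 = NULL) {
  if (is.null(t0)) t0 <- trajectory$time_s[1]
  if (!nrow(events))
    return(data.frame(dwell_s = numeric(0), direction = character(0)))
  tt <- events$time_s
  if (is.unsorted(tt)) stop("events must be sorted in time")
  if (any(diff(tt) <= 0)) stop("overlapping events")
  data.frame(dwell_s = diff(c(t0, tt)),
             direction = ifelse(events$size_nm > 0, "up", "down"))
}

#' Occupancy decomposition of an equilibrium hopping trace
#'
#' Fits the smoothed bead-height distribution with N + 1 Gaussian
#' components whose means are constrained to a uniform ladder
#' `base + n * step` (base and spacing refined in the fit, shared SD), by
#' expectation-maximisation. Peak weights and a hard assignment of every
#' sample to its most probable level yield the occupancy histogram handed
#' to [fit_unfolded_probability()].
#'
#' @param trajectory An `"mt_trajectory"` of an equilibrium hopping trace.
#' @param N Number of tandem domains, >= 1.
#' @param expected_step Expected single-domain step size, nm (initial
#'   ladder spacing).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return List of class `"height_fit"`: `histogram` (bin centres and
#'   densities with the fitted curve), `peaks` (mean, sd, weight per
#'   level), `base`, `step`, `sd`, `counts` (hard-assigned occupancy
#'   counts, n = 0..N), `converged`.
#' @export
occupancy_from_heights <- function(trajectory, N, expected_step,
                                   max_iter = 300, tol = 1e-8) {
  stopifnot(N >= 1, expected_step > 0)
  y <- trajectory$extension_smooth_nm
  if (is.null(y)) y <- trajectory$extension_nm
  ns <- 0:N
  base <- as.numeric(quantile(y, 0.005))
  step <- expected_step
  s <- max(mad(diff(y)) / sqrt(2), expected_step / 20, 1e-6)
  w <- rep(1 / (N + 1), N + 1)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- base + ns * step
    dens <- vapply(seq_along(ns), function(j) w[j] * dnorm(y, mu[j], s),
                   numeric(length(y)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: weighted least squares for the ladder (linear in base, step)
    Rn <- colSums(r)
    W <- sum(Rn)
    Sn <- sum(Rn * ns)
    Snn <- sum(Rn * ns^2)
    Sy <- sum(y)
    Sny <- sum((r %*% ns) * y)
    det <- W * Snn - Sn^2
    if (det > 0) {
      base <- (Snn * Sy - Sn * Sny) / det
      step <- (W * Sny - Sn * Sy) / det
    }
    mu <- base + ns * step
    s <- sqrt(max(sum(r * outer(y, mu, `-`)^2) / W, 1e-12))
    w <- Rn / W
  }
  if (step < 2 * s)
    warning("peaks closer than twice the noise SD: levels may be unresolved")
  assign_n <- ns[max.col(dens / tot, ties.method = "first")]
  counts <- as.integer(table(factor(assign_n, levels = ns)))
  h <- graphics::hist(y, breaks = "FD", plot = FALSE)
  fitted_curve <- rowSums(vapply(seq_along(ns), function(j)
    w[j] * dnorm(h$mids, base + ns[j] * step, s), numeric(length(h$mids))))
  structure(list(
    histogram = data.frame(center_nm = h$mids, density = h$density,
                           fitted = fitted_curve),
    peaks = data.frame(n = ns, mean_nm = base + ns * step, sd_nm = s,
                       weight = w),
    base = base, step = step, sd = s, counts = setNames(counts, ns),
    converged = converged),
    class = "height_fit")
}

#' @export
print.height_fit <- function(x, ...) {
  cat(sprintf("<height_fit> ladder base %.2f nm, step %.2f nm, sd %.2f nm\n",
              x$base, x$step, x$sd))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}
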