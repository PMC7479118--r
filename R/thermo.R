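# Equilibrium folding thermodynamics of N tandem two-state domains:
# binomial occupancy, force-dependent free energy, zero-force folding
# energy and critical force.

#' Binomial occupancy probability
#'
#' Probability of observing `n` unfolded domains out of `N` independent
#' identical two-state domains, each unfolded with probability `p`:
#' \eqn{P_N(n) = \binom{N}{n} p^n (1-p)^{N-n}}.
#'
#' @param n Number of unfolded domains, 0..N. Vectorised.
#' @param N Total number of tandem domains.
#' @param p Single-domain unfolded probability in `[0, 1]`.
#' @return Probability.
#' @export
binomial_occupancy <- function(n, N, p) {
  if (any(n < 0 | n > N)) stop("n must lie in 0..N")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  dbinom(n, N, p)
}

#' Fit the single-domain unfolded probability to an occupancy histogram
#'
#' Maximum-likelihood estimate of the binomial parameter from occupancy
#' counts: \eqn{\hat p = \sum_n n\,c_n / (N \sum_n c_n)} (closed form).
#' A least-squares fit of the normalised counts to the binomial pmf is
#' computed as a cross-check, and the standard error of \eqn{\hat p} comes
#' from bootstrap resampling of the raw occupancy labels. Estimates on the
#' boundary (all mass at n = 0 or n = N) are flagged, not clipped.
#'
#' @param counts Occupancy counts for n = 0..N (length N + 1).
#' @param N Number of tandem domains.
#' @param n_bootstrap Bootstrap resamples (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `"occupancy_fit"`: `counts`, `N`, `p`, `p_se`,
#'   `p_ls` (least-squares cross-check), `boundary` flag.
#' @export
fit_unfolded_probability <- function(counts, N, n_bootstrap = 1000,
                                     seed = NULL) {
  stopifnot(N >= 1)
  if (length(counts) != N + 1)
    stop("counts must have length N + 1 (n = 0..N)")
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  total <- sum(counts)
  ns <- 0:N
  p_hat <- sum(ns * counts) / (N * total)
  boundary <- p_hat %in% c(0, 1)
  # least-squares cross-check against the normalised histogram
  p_ls <- if (boundary) p_hat else
    optimize(function(p) sum((counts / total - dbinom(ns, N, p))^2),
             c(1e-9, 1 - 1e-9))$minimum
  p_se <- NA_real_
  if (n_bootstrap > 0 && !boundary) {
    if (!is.null(seed)) set.seed(seed)
    labels <- rep(ns, counts)
    p_se <- sd(vapply(seq_len(n_bootstrap), function(i)
      mean(sample(labels, replace = TRUE)) / N, numeric(1)))
  }
  structure(list(counts = counts, N = N, p = p_hat, p_se = p_se,
                 p_ls = p_ls, boundary = boundary),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> N = %d, p = %.4f +/- %.4f%s\n",
              x$N, x$p, x$p_se, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Force-dependent free-energy difference from the unfolded probability
#'
#' \eqn{\Delta G(F) = -k_B T \ln\frac{1 - p(F)}{p(F)}}, returned in kBT
#' units. Antisymmetric under \eqn{p \to 1 - p}; zero at p = 0.5.
#'
#' @param p Unfolded-state probability, strictly inside (0, 1). Vectorised.
#' @param env An [env_at()] environment (enters only through the unit
#'   convention; the value in kBT is temperature-free).
#' @return \eqn{\Delta G(F)} in kBT.
#' @export
free_energy_from_probability <- function(p, env) {
  stopifnot(inherits(env, "mt_env"))
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1); boundary p implies infinite energy")
  -log((1 - p) / p)
}

#' Standard error of the free energy from the probability error
#'
#' First-order propagation: \eqn{\sigma_{\Delta G} = \sigma_p / (p(1-p))}
#' in kBT.
#'
#' @param p Unfolded probability in (0, 1).
#' @param p_se Standard error of p.
#' @return Standard error of \eqn{\Delta G(F)} in kBT.
#' @export
dG_standard_error <- function(p, p_se) p_se / (p * (1 - p))

#' Zero-force folding free energy
#'
#' \eqn{\Delta G_0 = \Delta G(F) - \Delta\phi(F)} in kBT; the uncertainty
#' (when both errors are supplied) is the quadrature sum.
#'
#' @param dG_F Force-dependent free-energy difference, kBT.
#' @param dPhi_F Conformational free-energy difference, kBT.
#' @param dG_se,dPhi_se Optional standard errors, kBT.
#' @return \eqn{\Delta G_0} in kBT; if errors are given, the result carries
#'   an `se` attribute.
#' @export
zero_force_free_energy <- function(dG_F, dPhi_F, dG_se = NULL, dPhi_se = NULL) {
  stopifnot(is.finite(dG_F), is.finite(dPhi_F))
  out <- dG_F - dPhi_F
  if (!is.null(dG_se) && !is.null(dPhi_se))
    attr(out, "se") <- sqrt(dG_se^2 + dPhi_se^2)
  out
}

#' Critical force of a two-state domain
#'
#' The force at which folded and unfolded states are equally populated,
#' the root of \eqn{\Delta G_0 + \Delta\phi(F_c) = 0}. Unique because
#' \eqn{\Delta\phi} is monotone when the unfolded chain is longer than the
#' folded rod. Solved by bracketed root-finding on `(0, f_max]` to a
#' residual below `tol` kBT.
#'
#' @param dG0 Zero-force folding energy in kBT; must be negative for a
#'   domain that is folded at zero force.
#' @param unfolded [peptide_params()] of the unfolded chain.
#' @param folded [folded_domain_params()] of the folded domain.
#' @param env An [env_at()] environment.
#' @param f_max Upper search bound, pN.
#' @param tol Residual tolerance in kBT.
#' @return Critical force in pN. `dG0 >= 0` returns 0 with a warning; a
#'   missing root below `f_max` returns NA with a warning.
#' @export
critical_force <- function(dG0, unfolded, folded, env, f_max = 50,
                           tol = 1e-6) {
  if (dG0 >= 0) {
    warning("dG0 >= 0: domain unstable at zero force; critical force is 0")
    return(0)
  }
  g <- function(F) dG0 + conformational_free_energy(F, unfolded, folded, env)
  if (g(f_max) < 0) {
    warning("no critical force below f_max = ", f_max, " pN")
    return(NA_real_)
  }
  root <- uniroot(g, c(1e-3, f_max), tol = 1e-10)
  if (abs(root$f.root) > tol) warning("root residual exceeds tolerance")
  root$root
}

#' Temperature trend of the zero-force stability
#'
#' Tabulates \eqn{\Delta G_0} and \eqn{F_c} against temperature for a
#' series of equilibrium measurements taken at a common force, and reports
#' the sign of the trend in each.
#'
#' @param results `data.frame` with columns `temperature` (C), `force`
#'   (pN), `dG0` (kBT) and `Fc` (pN); >= 2 temperatures.
#' @param force_tol Forces differing by more than this are rejected unless
#'   `allow_mixed_forces` is set.
#' @param allow_mixed_forces Set to combine series at different forces.
#' @return List with the temperature-sorted `table` and trend labels
#'   `trend_dG0`, `trend_Fc` (`"increasing"`, `"decreasing"`, `"constant"`
#'   or `"non-monotone"`).
#' @export
temperature_series <- function(results, force_tol = 1e-6,
                               allow_mixed_forces = FALSE) {
  need <- c("temperature", "force", "dG0", "Fc")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (length(unique(results$temperature)) < 2)
    stop("need >= 2 distinct temperatures")
  if (!allow_mixed_forces &&
      diff(range(results$force)) > force_tol)
    stop("mixed forces: set allow_mixed_forces = TRUE to combine them")
  tab <- results[order(results$temperature), , drop = FALSE]
  trend <- function(x) {
    d <- diff(x)
    if (all(d == 0)) "constant"
    else if (all(d >= 0)) "increasing"
    else if (all(d <= 0)) "decreasing"
    else "non-monotone"
  }
  list(table = tab, trend_dG0 = trend(tab$dG0), trend_Fc = trend(tab$Fc))
}

#' Recompute the stability table from printed inputs
#'
#' Runs the thermodynamic chain on a table of measured inputs
#' (force, temperature, single-domain unfolded probability p with its
#' bootstrap error, and the conformational free energy with its
#' force-calibration error): computes \eqn{\Delta G(F)} from p,
#' \eqn{\Delta G_0 = \Delta G(F) - \Delta\phi(F)} with quadrature-summed
#' errors, and the critical force with its propagated error
#' \eqn{\sigma_{F_c} = \sigma_{\Delta G_0} k_B T / (x_u - x_f)(F_c)}.
#'
#' @param inputs `data.frame` with columns `domain` ("I27" or "SR4"),
#'   `force_pN`, `temperature_C`, `p`, `p_se`, `dphi_kBT`, `dphi_se`.
#'   Default: the packaged published measurement table, see
#'   [stability_inputs()].
#' @param domains Named list mapping domain labels to [domain_spec()]s.
#' @return The input table with computed columns `dG_kBT`, `dG_se`,
#'   `dG0_kBT`, `dG0_se`, `Fc_pN`, `Fc_se`.
#' @export
stability_table <- function(inputs = stability_inputs(),
                            domains = list(I27 = i27_domain(),
                                           SR4 = sr4_domain())) {
  out <- inputs
  nr <- nrow(inputs)
  out$dG_kBT <- out$dG_se <- out$dG0_kBT <- out$dG0_se <- NA_real_
  out$Fc_pN <- out$Fc_se <- NA_real_
  for (i in seq_len(nr)) {
    row <- inputs[i, ]
    dom <- domains[[row$domain]]
    if (is.null(dom)) stop("no domain spec for ", row$domain)
    env <- env_at(row$temperature_C)
    dG <- free_energy_from_probability(row$p, env)
    dG_se <- dG_standard_error(row$p, row$p_se)
    dG0 <- zero_force_free_energy(dG, row$dphi_kBT, dG_se, row$dphi_se)
    Fc <- critical_force(as.numeric(dG0), dom$unfolded, dom$folded, env)
    slope <- (peptide_extension(Fc, dom$unfolded, env) -
              folded_extension(Fc, dom$folded, env)) / env$kBT
    out$dG_kBT[i] <- dG
    out$dG_se[i] <- dG_se
    out$dG0_kBT[i] <- as.numeric(dG0)
    out$dG0_se[i] <- attr(dG0, "se")
    out$Fc_pN[i] <- Fc
    out$Fc_se[i] <- attr(dG0, "se") / slope
  }
  out
}
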