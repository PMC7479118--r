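# Boltzmann constant in pN nm / K
.kB <- 0.0138065

#' Thermal energy at a given temperature
#'
#' Converts a bath temperature in degrees Celsius to the thermal energy
#' \eqn{k_B T} in pN nm, the energy unit used throughout the package.
#'
#' @param temperature Temperature in degrees Celsius. Must be above
#'   absolute zero (-273.15 C).
#' @return Thermal energy in pN nm (about 4.09 at 23 C, 4.28 at 37 C).
#' @examples
#' kBT_at_temperature(23)
#' @export
kBT_at_temperature <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= -273.15))
    stop("temperature must be above absolute zero (-273.15 C)")
  .kB * (temperature + 273.15)
}

#' Experimental environment
#'
#' Bundles the bath temperature with its derived thermal energy. Celsius at
#' the interface, Kelvin only inside [kBT_at_temperature()].
#'
#' @param temperature Temperature in degrees Celsius.
#' @return An object of class `"mt_env"`: list with `temperature` (C) and
#'   `kBT` (pN nm).
#' @export
env_at <- function(temperature) {
  structure(list(temperature = temperature,
                 kBT = kBT_at_temperature(temperature)),
            class = "mt_env")
}

#' @export
print.mt_env <- function(x, ...) {
  cat(sprintf("<mt_env> %.2f C, kBT = %.4f pN nm\n", x$temperature, x$kBT))
  invisible(x)
}

#' Unfolded-peptide polymer parameters
#'
#' Worm-like-chain parameters of an unstructured polypeptide segment.
#' Defaults are the conventional values for unfolded protein: 0.38 nm of
#' contour per residue and a 0.8 nm bending persistence length.
#'
#' @param n_residues Number of residues in the segment (>= 0).
#' @param contour_per_residue Contour length per residue, nm.
#' @param persistence_length Bending persistence length, nm.
#' @return Object of class `"peptide_params"`.
#' @export
peptide_params <- function(n_residues,
                           contour_per_residue = 0.38,
                           persistence_length = 0.8) {
  stopifnot(length(n_residues) == 1, n_residues >= 0,
            contour_per_residue > 0, persistence_length > 0)
  structure(list(n_residues = n_residues,
                 contour_per_residue = contour_per_residue,
                 persistence_length = persistence_length),
            class = "peptide_params")
}

#' Folded-domain parameters
#'
#' A folded domain is modelled as a rigid rod of length `rod_length` (the
#' end-to-end distance of the folded structure along its attachment axis)
#' whose orientation is thermally averaged (Langevin function).
#'
#' @param rod_length Rod length in nm (>= 0).
#' @return Object of class `"folded_domain_params"`.
#' @export
folded_domain_params <- function(rod_length) {
  stopifnot(length(rod_length) == 1, rod_length >= 0)
  structure(list(rod_length = rod_length), class = "folded_domain_params")
}

#' DNA handle parameters
#'
#' Extensible worm-like-chain parameters of the double-stranded DNA handle
#' linking the construct to the bead. Defaults describe the 572-bp handle
#' used by the tethered-construct assays: persistence length 45 nm, stretch
#' modulus 1200 pN, helical rise 0.338 nm/bp.
#'
#' @param n_bp Number of base pairs.
#' @param persistence_length Bending persistence length, nm.
#' @param stretch_modulus Enthalpic stretch modulus, pN.
#' @param rise_per_bp Contour length per base pair, nm.
#' @return Object of class `"handle_params"`.
#' @export
handle_params <- function(n_bp = 572,
                          persistence_length = 45,
                          stretch_modulus = 1200,
                          rise_per_bp = 0.338) {
  stopifnot(n_bp > 0, persistence_length > 0, stretch_modulus > 0,
            rise_per_bp > 0)
  structure(list(n_bp = n_bp,
                 persistence_length = persistence_length,
                 stretch_modulus = stretch_modulus,
                 rise_per_bp = rise_per_bp),
            class = "handle_params")
}

#' Relative extension of a worm-like chain
#'
#' Inverts the Marko-Siggia interpolation formula
#' \deqn{\hat f = \hat x + \frac{1}{4(1-\hat x)^2} - \frac14}
#' for the relative extension \eqn{\hat x = x/L_c \in [0, 1)} at a
#' dimensionless force \eqn{\hat f = F L_p / k_B T}. The inversion is a
#' bracketed bisection, exact to `tol` in \eqn{\hat x}.
#'
#' @param f_hat Dimensionless force(s), >= 0. Vectorised.
#' @param tol Bisection tolerance in relative extension.
#' @return Relative extension(s) in `[0, 1)`; strictly increasing in `f_hat`.
#' @export
wlc_relative_extension <- function(f_hat, tol = 1e-12) {
  stopifnot(is.numeric(f_hat))
  if (any(f_hat < 0)) stop("f_hat must be non-negative")
  ms <- function(x) x + 1 / (4 * (1 - x)^2) - 0.25
  lo <- rep(0, length(f_hat))
  hi <- rep(1 - 1e-14, length(f_hat))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    below <- ms(mid) < f_hat
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[f_hat == 0] <- 0
  out
}

#' Extension of an unfolded peptide segment
#'
#' Mean worm-like-chain extension of an unstructured peptide at force
#' `force`: contour length times the inverted Marko-Siggia relative
#' extension at \eqn{\hat f = F L_p / k_B T}.
#'
#' @param force Force in pN, >= 0. Vectorised.
#' @param params A [peptide_params()] object.
#' @param env An [env_at()] environment.
#' @return Extension in nm.
#' @export
peptide_extension <- function(force, params, env) {
  stopifnot(inherits(params, "peptide_params"), inherits(env, "mt_env"))
  if (any(force < 0)) stop("force must be non-negative")
  Lc <- params$n_residues * params$contour_per_residue
  if (Lc == 0) return(rep(0, length(force)))
  Lc * wlc_relative_extension(force * params$persistence_length / env$kBT)
}

#' Extension of a folded domain
#'
#' Rigid rod of length d with free thermal orientation: the mean projection
#' along the force axis is \eqn{d\,[\coth(Fd/k_BT) - k_BT/(Fd)]} (Langevin
#' function), which vanishes at zero force and saturates at d.
#'
#' @param force Force in pN, >= 0. Vectorised.
#' @param params A [folded_domain_params()] object.
#' @param env An [env_at()] environment.
#' @return Extension in nm.
#' @export
folded_extension <- function(force, params, env) {
  stopifnot(inherits(params, "folded_domain_params"), inherits(env, "mt_env"))
  if (any(force < 0)) stop("force must be non-negative")
  d <- params$rod_length
  a <- force * d / env$kBT
  out <- numeric(length(force))
  big <- a > 1e-4
  out[big] <- d * (1 / tanh(a[big]) - 1 / a[big])
  out[!big] <- d * a[!big] / 3   # Langevin small-argument limit
  out
}

#' Extension of the DNA handle
#'
#' Extensible worm-like chain in the high-force (Odijk) approximation:
#' \deqn{x(F) = L_c \left[1 - \frac12\sqrt{\frac{k_BT}{F L_p}} +
#'   \frac{F}{S}\right].}
#' The approximation is only trusted above 0.5 pN; lower forces are
#' rejected rather than silently extrapolated.
#'
#' @param force Force in pN, > 0.5. Vectorised.
#' @param params A [handle_params()] object.
#' @param env An [env_at()] environment.
#' @return Extension in nm.
#' @export
handle_extension <- function(force, params, env) {
  stopifnot(inherits(params, "handle_params"), inherits(env, "mt_env"))
  if (any(force < 0.5))
    stop("handle extension model is only valid above 0.5 pN")
  Lc <- params$n_bp * params$rise_per_bp
  Lc * (1 - 0.5 * sqrt(env$kBT / (force * params$persistence_length)) +
          force / params$stretch_modulus)
}

#' Mechanical state of a tethered construct
#'
#' An ordered set of mechanical elements in series under a common force.
#' Each element is one of a peptide segment, a folded domain or a DNA
#' handle; the state's extension is the sum of element extensions.
#'
#' @param elements List of parameter objects ([peptide_params()],
#'   [folded_domain_params()] or [handle_params()]).
#' @param label Human-readable state label.
#' @return Object of class `"construct_state"`.
#' @export
construct_state <- function(elements = list(), label = "") {
  ok <- vapply(elements, function(e)
    inherits(e, c("peptide_params", "folded_domain_params", "handle_params")),
    logical(1))
  if (length(elements) && !all(ok))
    stop("elements must be peptide_params, folded_domain_params or handle_params")
  structure(list(elements = elements, label = label),
            class = "construct_state")
}

element_extension <- function(element, force, env) {
  if (inherits(element, "peptide_params"))
    peptide_extension(force, element, env)
  else if (inherits(element, "folded_domain_params"))
    folded_extension(force, element, env)
  else if (inherits(element, "handle_params"))
    handle_extension(force, element, env)
  else stop("unknown element kind")
}

#' Extension of a construct state
#'
#' Sum of the element extensions at a common force (series mechanics).
#'
#' @param state A [construct_state()].
#' @param force Force in pN. Vectorised.
#' @param env An [env_at()] environment.
#' @return Extension in nm (0 for an empty state).
#' @export
state_extension <- function(state, force, env) {
  stopifnot(inherits(state, "construct_state"))
  if (!length(state$elements)) return(rep(0, length(force)))
  Reduce(`+`, lapply(state$elements, element_extension, force = force,
                     env = env))
}

#' Predicted transition step size versus force
#'
#' Extension difference between two construct states over a force range --
#' the theoretical curve overlaid on force--step-size plots of rupture or
#' unfolding events.
#'
#' @param before,after [construct_state()] objects before and after the
#'   transition.
#' @param forces Forces in pN.
#' @param env An [env_at()] environment.
#' @return `data.frame` with columns `force_pN` and `step_nm`.
#' @export
step_size_curve <- function(before, after, forces, env) {
  data.frame(force_pN = forces,
             step_nm = state_extension(after, forces, env) -
                       state_extension(before, forces, env))
}

#' Conformational free-energy difference at force
#'
#' The force-dependent conformational free-energy difference between the
#' unfolded and folded states of one domain,
#' \deqn{\Delta\phi(F) = \int_0^F \left(x_u(f) - x_f(f)\right)\,df,}
#' evaluated by adaptive quadrature and returned in units of \eqn{k_B T}.
#' \eqn{x_u} is the worm-like-chain extension of the released peptide,
#' \eqn{x_f} the Langevin-averaged rod extension of the folded domain.
#'
#' @param force Upper integration limit in pN, >= 0. Vectorised.
#' @param unfolded [peptide_params()] of the unfolded chain.
#' @param folded [folded_domain_params()] of the folded domain.
#' @param env An [env_at()] environment.
#' @param rel_tol Quadrature relative tolerance.
#' @return \eqn{\Delta\phi(F)} in kBT; 0 at F = 0, non-decreasing in F
#'   wherever \eqn{x_u \ge x_f}.
#' @export
conformational_free_energy <- function(force, unfolded, folded, env,
                                       rel_tol = 1e-9) {
  stopifnot(inherits(unfolded, "peptide_params"),
            inherits(folded, "folded_domain_params"),
            inherits(env, "mt_env"))
  if (any(force < 0)) stop("force must be non-negative")
  integrand <- function(f)
    peptide_extension(f, unfolded, env) - folded_extension(f, folded, env)
  vapply(force, function(F) {
    if (F == 0) return(0)
    q <- stats::integrate(integrand, 0, F, rel.tol = rel_tol,
                          subdivisions = 500L)
    if (q$message != "OK")
      stop("quadrature failed: ", q$message,
           " (abs.error = ", signif(q$abs.error, 3), ")")
    q$value / env$kBT
  }, numeric(1))
}

#' Propagated uncertainty of the conformational free energy
#'
#' First-order propagation of the relative force-calibration uncertainty
#' into \eqn{\Delta\phi(F)}: since \eqn{d\Delta\phi/dF = x_u - x_f}, a
#' relative force error \eqn{\epsilon} gives
#' \eqn{\sigma_{\Delta\phi} = \epsilon F (x_u(F) - x_f(F)) / k_B T}.
#' Magnetic-bead force calibration carries about 10 percent relative
#' uncertainty, the default.
#'
#' @inheritParams conformational_free_energy
#' @param force_rel_err Relative force-calibration uncertainty.
#' @return Standard error of \eqn{\Delta\phi(F)} in kBT.
#' @export
dphi_standard_error <- function(force, unfolded, folded, env,
                                force_rel_err = 0.1) {
  dx <- peptide_extension(force, unfolded, env) -
        folded_extension(force, folded, env)
  force_rel_err * force * dx / env$kBT
}
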