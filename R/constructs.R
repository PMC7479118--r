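# Default mechanical parameters of the constructs studied with the pipeline.
# Rod lengths and peptide parameters are configurable stand-ins for values
# not printed with the experiments; they reproduce the published step sizes
# (see the methods vignette).

#' Default domain parameter sets
#'
#' Convenience constructors for the domains handled by the pipeline:
#' titin I27 (89 residues, 4.4 nm folded rod), the alpha-actinin spectrin
#' repeat SR4 (104 residues, 5.0 nm rod), and a designed helix-hairpin
#' (75 residues, 4.0 nm rod). Each returns a list with the unfolded-chain
#' [peptide_params()] and the folded-state [folded_domain_params()].
#'
#' @param n_residues Residues released on unfolding.
#' @param rod_length Folded end-to-end rod length, nm.
#' @return List with elements `unfolded` and `folded`.
#' @export
domain_spec <- function(n_residues, rod_length) {
  list(unfolded = peptide_params(n_residues), folded = folded_domain_params(rod_length))
}

#' @rdname domain_spec
#' @export
i27_domain <- function() domain_spec(89, 4.4)

#' @rdname domain_spec
#' @export
sr4_domain <- function() domain_spec(104, 5.0)

#' @rdname domain_spec
#' @export
helix_hairpin_domain <- function() domain_spec(75, 4.0)

#' Looped and unlooped states of the linker-looping construct
#'
#' The looping construct carries a DNA handle, four folded I27 spacer
#' domains, and two complementary helix-hairpin components (a, b) joined by
#' a long flexible linker. When a and b associate into the four-helix
#' bundle, the linker is looped and contributes no extension; rupture
#' releases the linker and (concurrently, as observed) unfolds the two
#' hairpins, so the unlooped state replaces the folded complex rod by an
#' unstructured chain of `linker_residues + complex_residues` residues.
#'
#' @param linker_residues Residues in the flexible loop linker (default 183,
#'   the FH1 linker length).
#' @param complex_residues Total residues of the two helix-hairpin
#'   components released by concurrent unfolding (default 150).
#' @param complex_rod Folded four-helix-bundle rod length, nm.
#' @param n_spacers Number of folded I27 spacer domains.
#' @param handle A [handle_params()] object.
#' @return List with [construct_state()] elements `looped` and `unlooped`.
#' @export
looping_construct_states <- function(linker_residues = 183,
                                     complex_residues = 150,
                                     complex_rod = 4.0,
                                     n_spacers = 4,
                                     handle = handle_params()) {
  spacers <- rep(list(folded_domain_params(4.4)), n_spacers)
  looped <- construct_state(
    c(list(handle), spacers, list(folded_domain_params(complex_rod))),
    label = "looped")
  unlooped <- construct_state(
    c(list(handle), spacers,
      list(peptide_params(linker_residues + complex_residues))),
    label = "unlooped+unfolded a,b")
  list(looped = looped, unlooped = unlooped)
}

#' Tandem-domain construct state with n domains unfolded
#'
#' State of a handle-tethered chain of `N` identical two-state domains with
#' `n_unfolded` of them unfolded: handle + (N - n) folded rods + one
#' unstructured peptide of `n * n_residues` residues.
#'
#' @param n_unfolded Number of unfolded domains, 0..N.
#' @param N Total number of tandem domains.
#' @param domain A [domain_spec()] (default [i27_domain()]).
#' @param handle A [handle_params()] object.
#' @return A [construct_state()].
#' @export
tandem_state <- function(n_unfolded, N = 4, domain = i27_domain(),
                         handle = handle_params()) {
  stopifnot(n_unfolded >= 0, n_unfolded <= N)
  folded <- rep(list(domain$folded), N - n_unfolded)
  els <- c(list(handle), folded)
  if (n_unfolded > 0) {
    pp <- domain$unfolded
    els <- c(els, list(peptide_params(n_unfolded * pp$n_residues,
                                      pp$contour_per_residue,
                                      pp$persistence_length)))
  }
  construct_state(els, label = sprintf("%d/%d unfolded", n_unfolded, N))
}

#' Calibrated default kinetics of the unzip-geometry complex rupture
#'
#' Bell parameters of the looped-complex rupture in the unzipping force
#' geometry. These defaults are calibrated, not measured: k0 = 1.85e-3 1/s
#' and delta_x = 1.88 nm place the modal rupture forces near 8, 12 and
#' 15 pN at loading rates of 0.2, 1 and 5 pN/s at 23 C, matching the
#' published force-ramp observables for this geometry.
#'
#' @return A [rate_params()].
#' @export
abzip_rupture_params <- function() rate_params(k0 = 1.85e-3, delta_x = 1.88)

#' Simulation configuration for the linker-looping construct
#'
#' One looped/unlooped [two_state_unit()] (the four I27 spacers stay
#' folded at ramp forces and enter as passive rods) with the calibrated
#' rupture kinetics of [abzip_rupture_params()] and no refolding during
#' pulling.
#'
#' @param env An [env_at()] environment.
#' @param rupture A [rate_params()] for the unlooping transition.
#' @param refold Optional [rate_params()] for looping.
#' @param ... Passed to [sim_config()] (noise, sampling, seed, ...).
#' @return A [sim_config()].
#' @export
looping_sim_config <- function(env = env_at(23),
                               rupture = abzip_rupture_params(),
                               refold = NULL, ...) {
  unit <- two_state_unit(
    label = "loop",
    folded = folded_domain_params(4.0),
    unfolded = peptide_params(333),
    unfold = rupture, refold = refold)
  sim_config(units = list(unit),
             extra = rep(list(folded_domain_params(4.4)), 4),
             env = env, ...)
}

#' Simulation configuration for a tandem-domain clamp experiment
#'
#' `N` identical, independently switching two-state domains behind the
#' DNA handle.
#'
#' @param N Number of tandem domains.
#' @param domain A [domain_spec()].
#' @param unfold,refold [rate_params()] of the per-domain transitions
#'   (`refold = NULL` for irreversible unfolding).
#' @param env An [env_at()] environment.
#' @param ... Passed to [sim_config()].
#' @return A [sim_config()].
#' @export
tandem_sim_config <- function(N = 4, domain = i27_domain(),
                              unfold, refold = NULL, env = env_at(23),
                              ...) {
  units <- lapply(seq_len(N), function(i)
    two_state_unit(label = sprintf("%s%d",
                                   if (domain$unfolded$n_residues == 104)
                                     "SR" else "dom", i),
                   folded = domain$folded, unfolded = domain$unfolded,
                   unfold = unfold, refold = refold))
  sim_config(units = units, env = env, ...)
}
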