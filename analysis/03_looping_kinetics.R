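#!/usr/bin/env Rscript
# Looping-formation kinetics from repeated force-jump cycles: simulate
# the waiting-time protocol at several hold forces, fit the two-state
# pairing-probability model, and extrapolate the looping rate to zero
# force from the printed rate pair.

suppressMessages(library(tethermech))
dir.create("results", showWarnings = FALSE)
seed <- 30L

env <- env_at(23)
# Bell laws behind the force-dependent looping/unlooping rates: the
# two-point solution of the printed k_p pair anchors the looping branch,
# and the weakly force-sensitive unlooping branch stays near 0.01 1/s
loop_law <- fit_bell(c(1.7, 2.9), c(0.58, 0.01), env)
unloop_law <- rate_params(0.005, 1.0)

dts <- c(2, 5, 10, 20, 40, 80)
hold_forces <- c(1.7, 2.0, 2.3, 2.6)
rows <- list()
for (Fh in hold_forces) {
  r <- looping_rates_at(Fh, loop_law, unloop_law, env)
  P <- vapply(seq_along(dts), function(i)
    mean(simulate_looping_cycles(r, dts[i], 100,
                                 seed = seed + round(Fh * 100) + i)$looped),
    numeric(1))
  fit <- fit_looping(dts, P, n_cycles = 100)
  message(sprintf(
    "hold %.1f pN: true (k_p, k_u) = (%.3f, %.4f); fitted (%.3f, %.4f)%s",
    Fh, r$k_p, r$k_u, fit$rates$k_p, fit$rates$k_u,
    if (fit$ill_conditioned) " [ill-conditioned]" else ""))
  rows[[length(rows) + 1]] <- data.frame(
    hold_force_pN = Fh, delta_t_s = dts, P_measured = P,
    P_fit = looping_probability(dts, fit$rates),
    k_p_fit = fit$rates$k_p, k_u_fit = fit$rates$k_u)
}
write.table(do.call(rbind, rows), "results/looping_probability.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "zero-force extrapolation of the printed pair: k_p(0) = %.0f 1/s, dx = %.1f nm",
  loop_law$k0, loop_law$delta_x))
message("(the published ~15.7 1/s extrapolation used four supplementary-only points;")
message(" the two printed rates alone give the value above)")

run_manifest("03_looping_kinetics", seed = seed,
             outputs = "results/looping_probability.tsv",
             path = "results/03_manifest.json")
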