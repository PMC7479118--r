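---
title: "Models and methods behind tethermech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tethermech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(tethermech)
```

tethermech analyses single-molecule magnetic-tweezers experiments on
tethered protein constructs: a superparamagnetic bead pulls on a chain of
mechanical elements — a double-stranded DNA handle, folded protein
domains, unstructured peptide segments, and (in the looping constructs) a
complex of two designed helix-hairpins whose association loops a long
flexible linker. The pipeline covers four layers: polymer mechanics,
force-dependent transition kinetics, equilibrium folding thermodynamics,
and trace analysis, with a stochastic trajectory generator that provides
ground truth for every downstream stage.

## Polymer mechanics

Each mechanical element contributes an extension at the applied force,
and extensions add in series (`state_extension()`).

**Unfolded peptide.** A worm-like chain with the Marko–Siggia
interpolation between the low- and high-force limits,
$\hat f = \hat x + \tfrac{1}{4(1-\hat x)^2} - \tfrac14$, where
$\hat f = F L_p / k_B T$ and $\hat x = x/L_c$. The map is inverted by
bracketed bisection to $10^{-12}$ in relative extension
(`wlc_relative_extension()`); the inversion is exact to far better than
any experimental resolution and the forward map reproduces $\hat f$ to
$10^{-8}$ across $\hat f \in [0, 10^3]$. Defaults: contour
0.38 nm/residue and persistence length 0.8 nm, the conventional values
for unstructured polypeptide. The interpolation formula itself
underestimates intermediate-force extension by up to ~10 % relative to
the exact worm-like chain; at the forces used here the bias is absorbed
by the effective persistence length, which is exposed in every
constructor for refitting.

**Folded domain.** A rigid rod of length $d$ with free thermal
orientation; the mean projection on the force axis is the Langevin
average $d[\coth(Fd/k_BT) - k_BT/(Fd)]$. Rod lengths default to 4.4 nm
(titin I27), 5.0 nm (α-actinin SR4) and 4.0 nm (helix-hairpin bundle).
These values are configurable stand-ins chosen to reproduce the
published unfolding step sizes (14.9 nm for I27 at 8 pN, ~17.9 nm for
SR4 near 8 pN); the experiments do not pin them independently.

**DNA handle.** The 572-bp handle uses the extensible worm-like chain in
the high-force (Odijk) form $x = L_c[1 - \tfrac12\sqrt{k_BT/FL_p} +
F/S]$ with $L_p = 45$ nm, $S = 1200$ pN, 0.338 nm/bp. The approximation
degrades below a fraction of a piconewton, so calls below 0.5 pN are
rejected rather than silently extrapolated — force-jump protocols that
park the construct at lower forces should model the handle separately.

**Free-energy integral.** The force-dependent conformational
free-energy difference between unfolded and folded states is
$\Delta\phi(F) = \int_0^F (x_u - x_f)\,df$, evaluated by adaptive
quadrature (`integrate`, relative tolerance $10^{-9}$) and checked in the
tests against a $10^4$-point trapezoid rule to $10^{-3}\,k_BT$. Its
dominant uncertainty is the ~10 % relative force-calibration error of
magnetic tweezers, propagated to first order as
$\sigma_{\Delta\phi} = 0.1\,F\,(x_u(F)-x_f(F))/k_BT$
(`dphi_standard_error()`); with the default polymer parameters this
reproduces the published $\Delta\phi$ error bars to a few per cent.

Temperature enters only through $k_BT$; polymer parameters are treated
as temperature-independent because no temperature dependence is
published for them.

## Rupture and looping kinetics

All force-dependent rates use the single-barrier Bell form
$k(F) = k_0 e^{F\Delta x / k_B T}$ with a signed transition distance —
the minimal law consistent with the Arrhenius treatment of these
experiments. `fit_bell()` is a least-squares line through $(F, \ln k)$,
which with two points is the closed-form two-point solution: the printed
looping-rate pair (0.58 s⁻¹ at 1.7 pN, 0.01 s⁻¹ at 2.9 pN) gives
$\Delta x \approx -13.8$ nm and $k_p(0) \approx 1.8\times10^2$ s⁻¹. The
published zero-force extrapolation (~15.7 s⁻¹) rests on four rate points
of which only these two are printed, so it is not reproducible here and
the two-point solution is reported instead.

Under a linear ramp at loading rate $r$ the rupture-force density is the
first-passage expression $p(F) = \frac{k(F)}{r}\exp(-\frac1r\int_{F_0}^F
k)$ with the closed-form Bell integral, computed in log space because
the hazard integral overflows double precision long after the density
has decayed. The modal force $(k_BT/\Delta x)\ln(r\Delta x / k_0 k_BT)$
grows linearly in $\ln r$; the trajectory generator's default rupture
kinetics ($k_0 = 1.85\times10^{-3}$ s⁻¹, $\Delta x = 1.88$ nm) are
**calibrated, not measured** — chosen once so the modal rupture forces
fall near the published ~8/~12/~15 pN at 0.2/1/5 pN/s in the unzipping
geometry.

Lifetimes are estimated by maximum likelihood (the sample mean —
unbiased and binning-free), with the common histogram practice
(Doane-rule bins, Poisson-weighted least squares against
$Ae^{-t/\tau}$) available as a cross-check mode; the reported standard
error is $\tau/\sqrt{n-1}$. The two estimators typically agree within
15 % at $n = 100$, but the binned fit carries real binning noise: the
suite asserts their median agreement, not every draw.

Looping kinetics follow the two-state relaxation
$P(\Delta t) = \frac{k_p}{k_p+k_u}(1 - e^{-(k_p+k_u)\Delta t})$.
`fit_looping()` profiles the weighted least squares over the total rate
(the plateau enters linearly, so the inner problem is closed-form),
then polishes with a full two-parameter Levenberg–Marquardt fit for
asymptotic errors. Weights are inverse binomial variances when cycle
counts are supplied. Designs in which no waiting time reaches one
relaxation time leave the plateau — and hence $k_u$ — unidentified; such
fits are flagged `ill_conditioned` rather than silently extrapolated.

A quantitative limit worth stating: with 6 waiting times at 100 cycles
each, binomial counting noise alone puts the achievable relative
precision of the total rate near 12–15 % (the per-point information on
$k_{tot}$ is bounded by $A\,k\Delta t\,e^{-k\Delta t} \le 0.37 A$).
Recovery of *both* rates to 15 % therefore succeeds in only ~40 % of
replicates at this design regardless of the true rates — a property of
the counting statistics, not of the estimator — and the acceptance suite
reports this rate honestly. Designs needing tighter rates should raise
the cycle count.

Two-population rupture-force histograms (the shear-geometry case, where
a partially folded intermediate coexists with the full four-helix
bundle) are decomposed by a two-component Gaussian mixture fitted with
expectation-maximisation: deterministic initialisation at the 30th/70th
percentiles, 500-iteration cap, $10^{-8}$ log-likelihood tolerance, the
higher-mean component labelled "strong", and a bootstrap standard error
on its weight. The deterministic initialisation makes the fit
reproducible and permutation-invariant; an independent EM (mclust)
serves as a cross-check in the tests.

## Equilibrium thermodynamics of tandem domains

With $N$ independent identical two-state domains, the number unfolded at
equilibrium follows the binomial law $P_N(n) = \binom{N}{n}p^n(1-p)^{N-n}$.
The single-domain unfolded probability is fitted by the closed-form
maximum-likelihood estimator $\hat p = \sum n c_n / (N\sum c_n)$ rather
than curve-fitting the occupancy bar graph: both agree for well-populated
histograms and the MLE is deterministic. Its uncertainty comes from
bootstrap resampling of the occupancy labels (1000 resamples by
default, seeded). Boundary estimates ($\hat p \in \{0,1\}$) are flagged,
never clipped. Note the bootstrap treats samples as independent; for
occupancies read off an autocorrelated trace it understates the error by
roughly the square root of the number of samples per relaxation time.

The free-energy chain is
$\Delta G(F) = -k_BT\ln\frac{1-p}{p}$,
$\Delta G_0 = \Delta G(F) - \Delta\phi(F)$, and the critical force
solves $\Delta G_0 + \Delta\phi(F_c) = 0$ by bisection-bracketed
root-finding on (0, 50] pN to a residual below $10^{-6}\,k_BT$ (unique
because $\Delta\phi$ is monotone whenever the unfolded contour exceeds
the rod length). Uncertainties propagate to first order: quadrature
sums for $\Delta G_0$, and $\sigma_{F_c} =
\sigma_{\Delta G_0} k_BT / (x_u - x_f)(F_c)$. Applied to the packaged
published inputs this chain reproduces every published
$\Delta G(F)$ cell to better than 0.005 $k_BT$, every $\Delta G_0$ cell
to 0.04 $k_BT$, and the critical forces within ~0.3 pN (the residual
$F_c$ spread reflects the stand-in polymer parameters inside
$\Delta\phi$).

## Synthetic trajectory generator

The generator simulates the construct as independent two-state units
(the same independence the binomial occupancy model assumes) over a
continuous-time Markov chain with exact Gillespie waiting times at
constant force, and exact inverse-integrated-hazard sampling of
first-passage forces under a ramp (closed form for Bell rates; refolding
is neglected during force-increase scans, where reverse rates only
fall). Looping cycles evolve a single loop/unloop unit from the unlooped
state for the waiting time and report the end state.

Acquisition is modelled as additive Gaussian white noise per sample
(default SD 6 nm on the raw channel at 50 Hz — calibrated so that
20-point smoothing leaves the ~1.3 nm jitter visible in published
traces), with an optional Ornstein–Uhlenbeck correlated mode, since real
bead noise is correlated and neither its magnitude nor the published
acquisition rate is printed. Smoothing is a centred boxcar of the stated
window — a documented stand-in for the unspecified "FFT smooth" dialect
of the instrument software. Event logs carry exact model step sizes;
noise applies to samples only, which is what makes the generator a
ground-truth oracle for the detectors.

What the generator does **not** emulate: instrument drift, camera blur
and aliasing, bead-size heterogeneity (the 10 % force error enters the
error model, not the traces), correlated multi-domain transitions, and
the slow force-dependence of refolding during ramps. Passing closure
tests therefore demonstrates the internal consistency of the analysis
chain under the stated noise model, not robustness to every artefact of
real data.

## Trace analysis

**Step detection** uses a sliding two-sample (Welch-type) mean
comparison: running means of the `window` (default 25) samples before
and after each point, normalised by the raw-noise standard error
estimated from the median absolute deviation of first differences.
Contiguous super-threshold runs yield one candidate each at the maximum
statistic (ties break toward the earlier sample), candidates closer than
one window keep the larger statistic, and sizes come from flanking
medians with steps below `min_step` (default 3× the window-averaged
noise SD) discarded. The detector was chosen over hidden-Markov
approaches for determinism and transparency; events closer than about
one window merge into a single detection of summed size, which sets the
recall ceiling at high transition rates.

**Ramp rupture extraction** takes the largest detected step per cycle as
the unlooping event — the linker release (~70–80 nm) dwarfs both domain
unfolding and the smooth worm-like-chain drift a ramp imprints on the
running means; the default `min_step` of 20 nm rejects the latter two.
Censored cycles (no step) are counted, not dropped silently.

**Occupancy decomposition** fits the smoothed bead-height distribution
with $N+1$ Gaussian components whose means are constrained to a uniform
ladder $b + n\,s$ (base and spacing refined in the fit) with a shared
standard deviation — bead noise is state-independent to first order.
The constrained M-step is a weighted linear regression, so the EM is
deterministic given its moment-based initialisation. Peaks closer than
twice the fitted SD are flagged as unresolved. Hard assignment of each
sample to its most probable level yields the occupancy histogram passed
to the binomial fit.

## Problem sizes and numerical choices

The shipped studies use desk-scale sizes chosen as the package's own
defaults: 2000-force first-passage samples for distribution checks
(Kolmogorov–Smirnov distances ~0.02), $10^5$ samples per loading rate
for modal-force regressions (fixed kernel bandwidth 0.6 pN shared across
rates so the kernel bias cancels in the slope), $10^4$ looping cycles
for the pairing-probability closure, 3000 s hopping traces at 50 Hz for
occupancy recovery, and 100 clamp traces of 2400 s for detector scoring.
Hopping kinetics in the occupancy fixtures ($k_u + k_f = 0.4$ s⁻¹ at
$p = 0.27$) were chosen so a trace holds ~600 relaxation times —
statistical error ~0.009 in $\hat p$, well inside the ±0.02 closure
tolerance — while keeping transitions slow relative to the smoothing
window. The detector fixture accelerates I27 unfolding (Bell
$k_0 = 5\times10^{-3}$ s⁻¹, $\Delta x = 0.6$ nm) so that four events fit
in a 2400 s trace while remaining well separated at the detector's
merging scale.

## Known limitations

- Polymer parameters and rod lengths are stand-ins; $\Delta\phi$ and
  $F_c$ inherit their uncertainty (the published values carry the same
  caveat through their Supplementary polymer models).
- The Bell law is single-barrier: no curvature in $\ln k(F)$, no
  loading-rate-dependent $\Delta x$, no free-energy-surface
  reconstruction.
- Domains are independent two-state units; cooperative or
  intermediate-bearing folding is out of scope.
- The step detector reports merged events for transitions inside one
  window, and the occupancy bootstrap understates errors on strongly
  autocorrelated traces (see above).
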