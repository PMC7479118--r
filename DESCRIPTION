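Package: tethermech
Title: Mechanics and Kinetics of Tethered Single-Molecule Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule magnetic-tweezers experiments
    on tethered protein constructs: worm-like-chain force-extension models of
    DNA handles, unfolded peptides and folded domains; predicted transition step
    sizes and the conformational free-energy integral; Bell-Arrhenius
    force-dependent rupture kinetics with analytic rupture-force distributions
    under constant loading rate; two-state looping kinetics; equilibrium
    binomial-occupancy folding thermodynamics of tandem domains (force-dependent
    free energy, zero-force folding energy and critical force); a stochastic
    bead-height trajectory generator with known ground truth; and trace-analysis
    tools (step detection, dwell times, rupture forces, bead-height occupancy
    decomposition) that close the loop from raw traces to fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
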