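Package: hvgate
Title: Allosteric Gating and Patch-Clamp Analysis for Voltage-Gated Proton Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium allosteric (MWC-style) model of voltage- and
    pH-gradient-dependent gating of Hv1-type proton channels, together with the
    standard electrophysiological fitting toolbox used to characterize them:
    Boltzmann conductance-voltage fits, threshold-voltage estimation,
    exponential-with-delay activation kinetics, Nernst and tail-current reversal
    potentials, p/4 leak subtraction, Woodhull voltage-dependent block and Hill
    dose-response fits for zinc inhibition, and a random-assembly dimer FRET
    stoichiometry model. Includes seeded generators of synthetic whole-cell and
    excised-patch proton-current families so the full analysis pipeline can be
    exercised end to end without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
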