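# hvgate

Quantitative analysis of voltage-gated proton (Hv1-type) channels: an
equilibrium allosteric model of voltage- and pH-gradient-dependent gating,
plus the complete patch-clamp fitting toolbox used to characterize these
channels — exercised end to end on seeded synthetic recordings.

## Who this is for

Channel biophysicists and electrophysiologists analysing proton-current
families: extracting conductance–voltage relations, activation kinetics,
reversal potentials, zinc-block parameters and FRET-based subunit
stoichiometry, and interpreting the pH-gradient dependence of gating through
an explicit allosteric mechanism.

## The model and the fits

Hv1 gating is modelled as an 8-state MWC scheme: one voltage-dependent
closed→open equilibrium K(V) = K_V(0)·exp(q_g·V/V_T), an external and an
internal proton-binding site with weights x = 10^(pK−pH), and couplings C
(external↔opening), D (internal↔opening) and E (site↔site). The
half-activation voltage has the closed form

    V0.5 = (V_T/q_g) · ln[ (1 + x_o + x_i + E·x_o·x_i)
                         / (Kv0·(1 + C·x_o + D·x_i + C·D·E·x_o·x_i)) ]

which reproduces the saturating, steeper-than-40 mV/ΔpH dependence of V0.5
on the pH gradient. Around the model sit the standard fits:

* Boltzmann G-V: G/Gmax = 1/(1 + exp(−q(V−V0.5)/V_T)) — `fit_boltzmann()`
* threshold voltage from the exponential foot G = G′·exp(qV/V_T) — `fit_threshold()`
* activation time course I(t) = Iss·(1 − exp(−(t−δ)/τ)) — `fit_activation_trace()`
* rate–voltage law k(V) = k(0)·exp(−V·q_k/V_T) — `fit_rate_voltage()`
* Nernst and tail-current reversal potentials — `nernst_potential()`, `reversal_from_tails()`
* p/4 leak subtraction — `p4_leak_subtract()`
* Woodhull block F_B = 1/(1 + exp(−δz(V−V0.5)/V_T)) and Hill dose-response
  F_B = 1/(1 + (K_D/[B])^n) — `fit_woodhull()`, `fit_hill()`
* random-assembly dimer FRET E_app = E_max/(1 + ρ·I_d/I_a) and Förster
  distance R = R0·(1/E − 1)^(1/6) — `fit_dimer_model()`, `forster_distance()`

Seeded generators (`generate_current_family()`, `generate_tail_family()`,
`generate_block_experiment()`, `generate_fret_population()`) produce
synthetic recordings with the statistical structure the analyses assume, and
`run_pipeline()` chains leak subtraction → G-V extraction → per-condition
fits → V0.5-vs-ΔpH assembly → model comparison. Units are fixed throughout:
mV, ms, pA, nS, kelvin, e₀, µM, Å.

## Worked example

Simulate a whole-cell proton-current family at ΔpH = 1 with leak and noise,
leak-subtract it, and recover the gating parameters:

```r
library(hvgate)

proto <- voltage_protocol(-60, seq(-50, 60, 10), 2000, 1, p4_n = 4)
fam <- generate_current_family(proto, list(v_half = 7.85, q = 2.09),
                               pH_o = 7, pH_i = 6, g_max_nS = 5,
                               g_leak_nS = 2, noise_sd_pA = 1, seed = 42)
fam <- p4_leak_subtract(fam)
gv  <- conductance_from_iv(steady_state_currents(fam), nernst_potential(7, 6))
fit_boltzmann(gv)
#> Boltzmann G-V fit: V0.5 = 7.852 mV, q = 2.09 e0, Gmax = 5
#>   se(V0.5) = 0.0152 mV, se(q) = 0.00209 e0
```

The fit recovers the generating midpoint (7.85 mV) and apparent gating
charge (2.09 e₀) within their standard errors, and the fitted Gmax matches
the configured 5 nS. The allosteric model itself:

```r
p <- amhv1_gating_params()   # published coral-channel parameter set
solve_v_half(p, pH_o = 7, pH_i = 6)
#> [1] 81.58051
v_half_vs_delta_ph(p, pH_o = rep(7, 4), pH_i = c(8, 7, 6, 5))
```

gives the model V0.5 per pH condition; `run_pipeline()` assembles the same
table from (simulated or recorded) current families and reports residuals
against the model curve.

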