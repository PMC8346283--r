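---
title: "Voltage- and pH-dependent gating analysis of Hv1-type proton channels"
author: "hvgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage- and pH-dependent gating analysis of Hv1-type proton channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgate)
```

## The scientific problem

Voltage-gated proton channels (Hv1) are single voltage-sensing domains that
conduct protons outward under physiological gradients. Their defining
behaviour is that the voltage range of activation is set not only by membrane
potential but by the transmembrane pH gradient, ΔpH = pH_o − pH_i: in most
orthologs the half-activation voltage V₀.₅ shifts by roughly −40 mV per unit
of ΔpH. `hvgate` implements (i) an equilibrium allosteric model that gives
this modulation a mechanistic basis, and (ii) the complete set of fitting
procedures used to characterize such channels from patch-clamp recordings,
together with seeded generators of synthetic recordings so the whole pipeline
can be exercised and validated without any measured data.

All quantities use a fixed unit system: mV, ms, pA, nS (so pA/mV = nS),
kelvin, elementary charges (e₀), µM, Å. The thermal voltage
$V_T = k_B T / e_0$ is ≈ 25.43 mV at the default temperature of 295.15 K
(22 °C), configurable everywhere.

## The allosteric gating model

The model is an MWC-style scheme with eight states. One voltage-dependent
equilibrium governs the closed→open transition,

$$K(V) = K_V(0)\, e^{q_g V / V_T},$$

with $K_V(0)$ the equilibrium constant at 0 mV and $q_g$ the gating charge.
Two saturable proton-binding sites — one facing the external solution, one
the internal — titrate with simple single-site equilibria; the bound:unbound
weight of a site is $x = 10^{pK - pH}$ (`binding_weight()`). Three coupling
constants tie the modules together: $C$ couples the external site to opening,
$D$ the internal site to opening, and $E$ the two sites to each other. The
statistical weight of each state, relative to the unbound closed state,
multiplies one factor per realized pairwise interaction:

| state | weight |
|---|---|
| C | 1 |
| CH_o | $x_o$ |
| CH_i | $x_i$ |
| CH_oH_i | $E x_o x_i$ |
| O | $K(V)$ |
| OH_o | $K(V)\,C\,x_o$ |
| OH_i | $K(V)\,D\,x_i$ |
| OH_oH_i | $K(V)\,C D E\, x_o x_i$ |

Because the weights are state functions, detailed balance holds around every
loop of the state graph by construction. The open probability is the ratio of
the open-tier sum to the full partition sum; it is evaluated in log space
(log-sum-exp) so it is well behaved at any finite voltage. Because the scheme
has a single voltage-dependent step, the open probability at fixed pH is
exactly a Boltzmann function of voltage with charge $q_g$; protonation only
shifts its midpoint. That midpoint has the closed form

$$V_{0.5} = \frac{V_T}{q_g}\,
  \ln\frac{1 + x_o + x_i + E x_o x_i}
          {K_V(0)\,\bigl(1 + C x_o + D x_i + C D E x_o x_i\bigr)},$$

implemented in `solve_v_half()` and verified in the tests against a numeric
root of the open probability to 10⁻⁶ mV, with the open probability itself
checked against a brute-force enumeration of all eight states (10⁻¹²
relative tolerance over 1000 random parameter draws).

With the published coral-channel parameter set (`amhv1_gating_params()`:
$E = 5\times10^5$, $D = 10^5$, $C = 2\times10^{-4}$,
$K_V(0) = 5\times10^{-5}$, $q_g = 1\,e_0$, $pK_o = 3.4$, $pK_i = 7$) the
V₀.₅–ΔpH relation is sigmoidal: monotone decreasing, steeper than
40 mV per pH unit in its mid-section, and saturating at both extremes
because both sites titrate fully. An inhibitory external site ($C < 1$) and
an excitatory internal site ($D > 1$) are what the sign of the ΔpH dependence
requires.

```{r sweep}
p <- amhv1_gating_params()
sw <- v_half_vs_delta_ph(p, pH_o = rep(7, 7), pH_i = seq(4, 10, 1))
sw
```

The construction of the state weights (the placement of $E$ in both
conformations, and $Q = 10^{pK-pH}$ as the protonation weight) is the
canonical MWC bookkeeping; it is a design choice of this package. Note that
with the published parameter set the model's absolute V₀.₅ at pH_o 7 / pH_i 6
(≈ 82 mV) sits well above typical measured values at ΔpH = 1 (≈ 8 mV); the
parameter set is used here as printed, for the shape of the ΔpH relation,
and no refit to data is attempted (no data table exists to fit). The model is
equilibrium-only: activation kinetics are described empirically (below), not
by rate constants on the state graph; dimer cooperativity is likewise out of
scope.

## Electrophysiological fitting procedures

**Conductance.** Steady-state currents are converted assuming ohmic
instantaneous currents, $I(V) = G (V - V_{rev})$, with $V_{rev}$ either the
proton Nernst potential $-\ln(10) V_T \Delta pH$ (`nernst_potential()`) or
interpolated from an instantaneous tail-current I-V
(`reversal_from_tails()`). A 1 mV guard band around $V_{rev}$ rejects
ill-conditioned points.

**Boltzmann G-V** (`fit_boltzmann()`):
$G/G_{max} = 1/(1 + e^{-q(V - V_{0.5})/V_T})$, written with the negative
exponent so conductance rises with depolarization. For unnormalized curves
$G_{max}$ is a free parameter — dividing by the largest observed point biases
the fit whenever saturation is incomplete — and per-point sem weights are
used when available.

**Threshold voltage** (`fit_threshold()`): the rising foot of the G-V
(default $G/G_{max} \le 0.3$) is fitted to $G = G' e^{qV/V_T}$ and the
apparent threshold is the voltage at which the fit reaches a fraction
(default 10%) of $G_{max}$. The threshold is less sensitive than V₀.₅ to
distortion of the curve's top by proton depletion.

**Activation kinetics** (`fit_activation_trace()`):
$I(t) = I_{ss}(1 - e^{-(t-\delta)/\tau})$, the exponential-with-delay form;
a non-zero delay is the signature of a multi-state activation path, and
delay < time constant indicates a late rate-limiting step. The conventional
fit window is the second half of the pulse; the window is an explicit
parameter and is recorded in the fit, because a delay estimated from a late
window is an extrapolation. Numerically, windows confined to the settled
plateau leave $(\tau, \delta)$ nearly unidentifiable, so the fitter tries a
log-linearized starting estimate first and falls back to a short ladder of
heuristic starts. The voltage dependence of either parameter is fitted as
$k(V) = k(0) e^{-V q_k / V_T}$ (`fit_rate_voltage()`), by default on the log
scale where the model is linear (exact for clean data, robust under noise);
direct nonlinear fitting is available.

**p/4 leak subtraction** (`p4_leak_subtract()`): each test pulse of amplitude
$\Delta V$ is accompanied by $N$ sub-threshold pulses of amplitude
$\Delta V / N$; the corrected trace is raw − N × (mean subsweep response).
Traces follow the holding-current-zeroed convention (the leak component of a
record is $g_{leak}(V - V_{hold})$), so a purely ohmic cell yields exactly
zero after correction. A single full-amplitude subsweep subtracts channel
current along with the leak; the function warns about this misuse.

**Zinc block.** The fraction blocked, $F_B = 1 - I/I_{control}$, is fitted to
the Woodhull model
$F_B(V) = 1/(1 + e^{-\delta z (V - V_{0.5})/V_T})$, describing a charged
blocker bound at an electrical distance $\delta$ into the field. Since
$\delta$ and the valence $z$ enter only through their product, $z$ is always
held fixed (2 for zinc) and the identifiable effective charge $z\delta$ is
reported alongside. The fit runs internally in the logistic's linear
parametrization $(a, b)$ — which remains well-conditioned when the block is
voltage-independent ($b \to 0$, where the half-block voltage is undefined and
reported as `NA`) — and transforms back with delta-method covariance.
Out-of-range $F_B$ values from noise are retained during fitting (clipping
would bias the estimates) and only clipped in reports. The dose-response is
fitted on the linear scale to the Hill form
$F_B = 1/(1 + (K_D/[B])^{n_H})$, with concentrations ideally log-spaced over
two or more decades.

**FRET stoichiometry.** Under random assembly of donor- and acceptor-tagged
subunits into dimers, a donor's partner is an acceptor with probability
$1/(1 + \rho\, r)$, where $r = I_d/I_a$ and $\rho$ is the acceptor-to-donor
brightness ratio, giving $E_{app} = E_{max}/(1 + \rho r)$. Cells are binned
into ratio windows (default width 0.1, mean ± sem per bin) and the two
parameters fitted with bins weighted by occupancy — sparse single-cell tail
bins would otherwise dominate. Bin averaging on a convex curve carries a
small Jensen bias, so `bin_width = NULL` fits the per-cell points directly
and recovers noise-free populations exactly. The module consumes
already-computed $(I_d, I_a, E_{app})$ triplets; spectral unmixing and
direct-excitation corrections belong to the acquisition pipeline, not here.
The pairwise efficiency converts to a fluorophore separation via
$R = R_0 (1/E - 1)^{1/6}$; $R_0$ is a configuration input with no default
asserted, and every report prints the $R_0$ used.

## The synthetic-data generators

`generate_current_family()` composes the forward models above: steady-state
channel current $G_{max} P(V) (V - V_{rev})$ with $P$ from a Boltzmann or
allosteric source, exponential-with-delay rise (exactly zero before the
delay, which is where the two-parameter time-course form is undefined),
ohmic driving force with a Nernstian reversal potential, linear leak, white
Gaussian noise, and optional p/4 subsweeps. Deactivation tails are
instantaneous jumps followed by mono-exponential decay with a configurable
tail time constant (the analyses only use the instantaneous amplitude).
Subsweep responses are idealized as purely linear: they are taken from a
sub-threshold holding level where the open probability is negligible, and the
idealization gives the corrected family a known exact decomposition for
testing. Every generator is a deterministic function of its configuration
and seed, and seeding is local (the caller's RNG stream is untouched).

What the generators deliberately omit — capacitive transients, series
resistance, proton depletion during large currents, 1/f noise, stochastic
single-channel gating — bounds what the passing tests show: they validate
the estimators against the stated models of the measurement, not against
every artifact of a real rig. Default study conditions mirror the
characterization they emulate: 10 mV voltage grids (−50…60 mV for the coral
channel, wider for the human one), 22 °C, ΔpH around 1, 134-cell FRET
populations with lognormal expression ratios, zinc doses log-spaced over
1–1000 µM.

## The end-to-end pipeline

`run_pipeline()` chains the stages — optional p/4 subtraction, steady-state
extraction, conductance conversion, Boltzmann and threshold fits per pH
condition, assembly of the (ΔpH, V₀.₅, V_Thr) table, and comparison against
the allosteric prediction (`compare_model_to_vhalf()`, per-point residuals
and RMS). It consumes either trace tables on disk (wide TSV plus JSON
metadata sidecar, written and read bit-stably by `write_current_family()` /
`read_current_family()`) or a simulation block. When simulating without an
explicit protocol, each condition's pulse grid is centred on the
model-predicted V₀.₅ (± 60 mV in 10 mV steps), as an experimenter would
choose, and grid points inside the reversal-potential guard band are dropped.
Results carry provenance: the seed, an MD5 hash of the configuration, and
the package version. Replicate recordings at one ΔpH are kept as individual
rows so every number remains traceable to its input; summaries combine them
as mean ± sem.

```{r pipeline}
cfg <- list(simulate = list(
  conditions = list(list(pH_o = 7, pH_i = 8), list(pH_o = 7, pH_i = 7),
                    list(pH_o = 7, pH_i = 6), list(pH_o = 7, pH_i = 5)),
  gating = amhv1_gating_params(), g_max_nS = 5, noise_sd_pA = 1))
res <- run_pipeline(cfg, seed = 11)
res
```

## Numerical choices and limitations

* Nonlinear least squares uses Levenberg–Marquardt (`minpack.lm::nlsLM`),
  which is robust at zero residual; linearizable fits (rate-voltage, logistic
  starting values) go through `lm`. Near-zero starting values are snapped to
  exactly zero because parameter-scaled numeric-derivative steps underflow.
* `open_probability` is exact in log space at any voltage; raw
  `state_weights` can overflow only beyond |V| of order 10⁵ mV.
* Root finding for the threshold voltage brackets around the closed-form
  V₀.₅ and expands until a sign change, tolerance 10⁻⁹ mV.
* Degenerate inputs fail loudly: flat G-V curves, decaying traces passed to
  the activation fit, tail I-Vs that never change sign, single-concentration
  dose tables, fewer than three foot points or ratio bins.
* Test problem sizes are chosen to finish in seconds while keeping the
  checks sharp: 1000 random draws for the enumeration oracle, 100–200 seeded
  replicates per noise study, a four-condition end-to-end study.
* The package fits equilibrium and empirical-kinetic descriptions; it does
  not simulate time-dependent state occupancy, vendor binary trace formats,
  or blocker kinetics (zinc block on/off is treated as instantaneous, as the
  wash experiments justify).
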