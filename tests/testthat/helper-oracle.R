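# Brute-force oracle for the allosteric model: enumerate all 8 states by
# looping over (conformation, external occupancy, internal occupancy) and
# multiplying one factor per realized pairwise interaction. Kept deliberately
# independent of the package's log-space partition-ratio implementation.
oracle_popen <- function(params, V, pH_o, pH_i) {
  VT <- 8.617333262e-2 * params$temperature_K
  xo <- 10^(params$pK_o - pH_o)
  xi <- 10^(params$pK_i - pH_i)
  K <- params$Kv0 * exp(params$q_g * V / VT)
  open_sum <- 0
  closed_sum <- 0
  for (open in 0:1) for (bo in 0:1) for (bi in 0:1) {
    w <- K^open * params$C^(open * bo) * params$D^(open * bi) *
      params$E^(bo * bi) * xo^bo * xi^bi
    if (open == 1) open_sum <- open_sum + w else closed_sum <- closed_sum + w
  }
  open_sum / (open_sum + closed_sum)
}

# random but well-conditioned parameter draws for property tests
random_params <- function() {
  allosteric_params(
    Kv0 = 10^stats::runif(1, -6, -1),
    q_g = stats::runif(1, 0.5, 2),
    C = 10^stats::runif(1, -4, 2),
    D = 10^stats::runif(1, -2, 5),
    E = 10^stats::runif(1, -2, 6),
    pK_o = stats::runif(1, 2, 9),
    pK_i = stats::runif(1, 2, 9),
    temperature_K = stats::runif(1, 278, 310)
  )
}

# published fit-parameter sets used across tests (G-V, kinetics, block)
fig_gv <- list(v_half = 7.85, q = 2.09)
fig_gv_h_long <- list(v_half = 34.1, q = 1.47)
fig_kin <- list(tau0 = 212, q_tau = 0.37, delta0 = 98.2, q_delta = 0.47)
fig_woodhull <- list(delta = 0.19, z = 2, v_half = 77.6)
fig_hill <- list(KD = 27.4, n = 0.48)

boltzmann_g <- function(V, v_half, q, temperature_K = 295.15) {
  1 / (1 + exp(-q * (V - v_half) / thermal_voltage(temperature_K)))
}
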