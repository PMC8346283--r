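# Run code with a local RNG state: seeds reproducibly without disturbing the
# caller's random stream. seed = NULL uses (and advances) the global stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Open probability of the configured gating source at voltage V.
# source: either an allosteric_params object, or a list with v_half, q
# (Boltzmann) — the two gating descriptions the analyses use.
.gating_popen <- function(source, V, pH_o, pH_i, temperature_K) {
  if (inherits(source, "allosteric_params")) {
    open_probability(source, V, pH_o, pH_i)
  } else {
    VT <- thermal_voltage(temperature_K)
    1 / (1 + exp(-source$q * (V - source$v_half) / VT))
  }
}

#' Generate a synthetic proton-current family
#'
#' Forward simulation of a voltage-clamp experiment on an Hv1-like channel:
#' at each test potential V the steady-state channel current is
#' \eqn{I_{ss} = G_{max} P(V) (V - V_{rev})} with P from a Boltzmann or
#' allosteric gating source and an ohmic driving force; the time course rises
#' as \eqn{I_{ss}(1 - e^{-(t - \delta(V))/\tau(V)})} for t > delta(V) and is
#' exactly zero before the delay; the kinetic parameters follow
#' \eqn{k(V) = k(0) e^{-V q_k / V_T}}. A linear leak
#' \eqn{g_{leak}(V - V_{hold})} (holding-current-zeroed convention) and white
#' Gaussian noise are added on top. When the protocol declares p/4 subsweeps,
#' each test pulse gets N scaled sub-threshold subsweeps whose responses are
#' purely linear (channels do not open at sub-threshold potentials), so p/4
#' subtraction recovers the channel current exactly.
#'
#' @param protocol A [voltage_protocol()].
#' @param gating Gating source: an [allosteric_params()] object, or a list
#'   \code{list(v_half = , q = )} for a Boltzmann source.
#' @param pH_o,pH_i Recording pH on each side.
#' @param kinetics List \code{list(tau0 = , q_tau = , delta0 = , q_delta = )}
#'   (ms, e0, ms, e0).
#' @param g_max_nS Maximal channel conductance, nS.
#' @param g_leak_nS Linear leak conductance, nS.
#' @param v_rev_mV Reversal potential; default the Nernst potential for the
#'   given pH gradient.
#' @param noise_sd_pA Standard deviation of the additive Gaussian noise.
#' @param temperature_K Temperature, kelvin.
#' @param configuration Recording configuration label.
#' @param seed Seed for the noise; recorded in the family metadata. The same
#'   seed yields a bit-identical family.
#' @return A [current_family()].
#' @export
generate_current_family <- function(protocol, gating, pH_o, pH_i,
                                    kinetics = list(tau0 = 50, q_tau = 0.37,
                                                    delta0 = 10, q_delta = 0.47),
                                    g_max_nS = 5, g_leak_nS = 0,
                                    v_rev_mV = NULL, noise_sd_pA = 0,
                                    temperature_K = 295.15,
                                    configuration = "whole-cell",
                                    seed = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            g_max_nS >= 0, g_leak_nS >= 0, noise_sd_pA >= 0)
  if (is.null(v_rev_mV)) v_rev_mV <- nernst_potential(pH_o, pH_i, temperature_K)
  tt <- seq(protocol$dt_ms, protocol$duration_ms, by = protocol$dt_ms)
  VT <- thermal_voltage(temperature_K)
  .with_seed(seed, {
    mk_chan <- function(V) {
      P <- .gating_popen(gating, V, pH_o, pH_i, temperature_K)
      iss <- g_max_nS * P * (V - v_rev_mV)
      tau <- kinetics$tau0 * exp(-V * kinetics$q_tau / VT)
      del <- kinetics$delta0 * exp(-V * kinetics$q_delta / VT)
      ifelse(tt > del, iss * (1 - exp(-(tt - del) / tau)), 0)
    }
    traces <- vapply(protocol$test_mV, function(V) {
      mk_chan(V) + g_leak_nS * (V - protocol$holding_mV) +
        if (noise_sd_pA > 0) stats::rnorm(length(tt), 0, noise_sd_pA) else 0
    }, numeric(length(tt)))
    subsweeps <- NULL
    if (protocol$p4_n > 0) {
      n <- protocol$p4_n
      subsweeps <- lapply(protocol$test_mV, function(V) {
        # sub-threshold steps of amplitude (V - V_hold)/N: linear response only
        resp <- g_leak_nS * ((V - protocol$holding_mV) / n)
        m <- matrix(rep(resp, length(tt) * n), nrow = length(tt))
        if (noise_sd_pA > 0)
          m <- m + matrix(stats::rnorm(length(tt) * n, 0, noise_sd_pA / n),
                          nrow = length(tt))
        m
      })
    }
    current_family(time_ms = tt, traces = traces, protocol = protocol,
                   pH_o = pH_o, pH_i = pH_i, temperature_K = temperature_K,
                   configuration = configuration, subsweeps = subsweeps,
                   extra = list(seed = seed, v_rev_mV = v_rev_mV,
                                g_max_nS = g_max_nS, g_leak_nS = g_leak_nS,
                                noise_sd_pA = noise_sd_pA))
  })
}

#' Generate a synthetic tail-current family
#'
#' An activating prepulse opens the channels to P(prepulse); the family then
#' steps to a grid of tail potentials. The instantaneous tail current at each
#' potential is \eqn{G_{max} P(V_{pre}) (V_{tail} - V_{rev})} — the
#' conductance has not yet relaxed, so the instantaneous I-V is linear and
#' crosses zero at the reversal potential — after which the current decays
#' mono-exponentially with a configurable deactivation time constant.
#'
#' @param tail_mV Grid of tail potentials, mV; must straddle the reversal
#'   potential for downstream reversal estimation.
#' @param prepulse_mV Activating prepulse potential, mV.
#' @param gating,pH_o,pH_i,g_max_nS,v_rev_mV,noise_sd_pA,temperature_K,seed
#'   As in [generate_current_family()].
#' @param tail_tau_ms Deactivation time constant, ms.
#' @param duration_ms,dt_ms Tail-segment length and sampling interval, ms.
#' @return A [current_family()] whose traces start at the step to the tail
#'   potential; read the instantaneous I-V with [instantaneous_iv()].
#' @export
generate_tail_family <- function(tail_mV, prepulse_mV, gating, pH_o, pH_i,
                                 g_max_nS = 5, v_rev_mV = NULL,
                                 tail_tau_ms = 20, duration_ms = 100,
                                 dt_ms = 0.5, noise_sd_pA = 0,
                                 temperature_K = 295.15, seed = NULL) {
  if (is.null(v_rev_mV)) v_rev_mV <- nernst_potential(pH_o, pH_i, temperature_K)
  P <- .gating_popen(gating, prepulse_mV, pH_o, pH_i, temperature_K)
  protocol <- voltage_protocol(holding_mV = prepulse_mV, test_mV = tail_mV,
                               duration_ms = duration_ms, dt_ms = dt_ms)
  tt <- seq(0, duration_ms, by = dt_ms)
  .with_seed(seed, {
    traces <- vapply(tail_mV, function(V) {
      i0 <- g_max_nS * P * (V - v_rev_mV)
      i0 * exp(-tt / tail_tau_ms) +
        if (noise_sd_pA > 0) stats::rnorm(length(tt), 0, noise_sd_pA) else 0
    }, numeric(length(tt)))
    # time base must be strictly increasing and start at the step
    current_family(time_ms = tt + 1e-9, traces = traces, protocol = protocol,
                   pH_o = pH_o, pH_i = pH_i, temperature_K = temperature_K,
                   extra = list(seed = seed, v_rev_mV = v_rev_mV,
                                prepulse_mV = prepulse_mV,
                                p_open_prepulse = P))
  })
}

#' Generate a synthetic zinc-block experiment
#'
#' Produces a control current family, the same family under blocker with each
#' trace scaled by \eqn{1 - F_B(V)} from the Woodhull model, and a Hill
#' dose-response table at a fixed voltage.
#'
#' @param protocol,gating,pH_o,pH_i,kinetics,g_max_nS,noise_sd_pA,temperature_K,seed
#'   As in [generate_current_family()].
#' @param woodhull List \code{list(delta = , z = , v_half = )} for the
#'   voltage-dependent block.
#' @param hill List \code{list(KD = , n = )} for the dose-response.
#' @param conc_uM Blocker concentrations for the dose table, uM; a zero
#'   concentration row yields F_B = 0.
#' @param dose_noise_sd Gaussian noise on the dose-table fractions.
#' @return List with elements \code{control} and \code{blocked}
#'   ([current_family()] objects) and \code{dose} (data frame
#'   \code{conc_uM}, \code{F_B}).
#' @export
generate_block_experiment <- function(protocol, gating, pH_o, pH_i,
                                      woodhull = list(delta = 0.19, z = 2,
                                                      v_half = 77.6),
                                      hill = list(KD = 27.4, n = 0.48),
                                      conc_uM = 10^seq(0, 3, length.out = 8),
                                      kinetics = list(tau0 = 50, q_tau = 0.37,
                                                      delta0 = 10, q_delta = 0.47),
                                      g_max_nS = 5, noise_sd_pA = 0,
                                      dose_noise_sd = 0,
                                      temperature_K = 295.15, seed = NULL) {
  .with_seed(seed, {
    control <- generate_current_family(protocol, gating, pH_o, pH_i,
                                       kinetics = kinetics,
                                       g_max_nS = g_max_nS,
                                       noise_sd_pA = noise_sd_pA,
                                       temperature_K = temperature_K,
                                       configuration = "outside-out",
                                       seed = NULL)
    fb <- woodhull_fraction(protocol$test_mV, woodhull$delta, woodhull$z,
                            woodhull$v_half, temperature_K)
    blocked <- control
    blocked$traces <- sweep(control$traces, 2, 1 - fb, `*`)
    blocked$extra$woodhull <- woodhull
    dose <- data.frame(conc_uM = conc_uM,
                       F_B = ifelse(conc_uM > 0,
                                    hill_fraction(pmax(conc_uM, .Machine$double.xmin),
                                                  hill$KD, hill$n), 0))
    if (dose_noise_sd > 0)
      dose$F_B <- dose$F_B + stats::rnorm(nrow(dose), 0, dose_noise_sd)
    list(control = control, blocked = blocked, dose = dose)
  })
}

#' Generate a synthetic FRET cell population
#'
#' Draws per-cell donor/acceptor expression ratios from a lognormal
#' distribution, computes the apparent FRET efficiency from the
#' random-assembly dimer model and adds Gaussian measurement noise.
#'
#' @param n_cells Number of cells (>= 1).
#' @param e_max,rho Dimer model parameters ([dimer_eapp()]).
#' @param ratio_meanlog,ratio_sdlog Lognormal parameters of the I_d/I_a
#'   expression ratio across cells.
#' @param noise_sd Gaussian noise on the apparent efficiency.
#' @param seed Seed; same seed gives an identical population.
#' @return Data frame with columns \code{I_d}, \code{I_a}, \code{E_app}.
#' @export
generate_fret_population <- function(n_cells, e_max = 0.35, rho = 1,
                                     ratio_meanlog = log(0.8),
                                     ratio_sdlog = 0.6,
                                     noise_sd = 0.03, seed = NULL) {
  stopifnot(n_cells >= 1, noise_sd >= 0, ratio_sdlog >= 0)
  .with_seed(seed, {
    ratio <- stats::rlnorm(n_cells, ratio_meanlog, ratio_sdlog)
    I_a <- stats::rlnorm(n_cells, log(1000), 0.3)
    e <- dimer_eapp(ratio, e_max, rho) +
      if (noise_sd > 0) stats::rnorm(n_cells, 0, noise_sd) else 0
    data.frame(I_d = ratio * I_a, I_a = I_a, E_app = e)
  })
}
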