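#' Thermal voltage k_B*T/e0 in millivolts
#'
#' The natural voltage scale of gating equations: the Boltzmann constant times
#' absolute temperature divided by the elementary charge. At 22 degrees C
#' (295.15 K) it is approximately 25.434 mV.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 295.15 K (22 C).
#' @return Thermal voltage in mV.
#' @examples
#' thermal_voltage()          # ~25.43 mV
#' thermal_voltage(310.15)    # body temperature
#' @export
thermal_voltage <- function(temperature_K = 295.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  # k_B/e0 = 8.617333262e-5 V/K = 8.617333262e-2 mV/K (2018 CODATA)
  8.617333262e-2 * temperature_K
}

#' Parameter set of the allosteric proton-channel gating model
#'
#' Builds and validates the parameter set of the equilibrium allosteric (MWC
#' style) model of voltage- and pH-dependent gating. The channel has one
#' voltage-dependent closed-open transition with equilibrium constant
#' \eqn{K(V) = K_{V}(0) \exp(q_g V / V_T)}, one extracellular and one
#' intracellular proton-binding site with acid-dissociation exponents
#' \code{pK_o} and \code{pK_i}, and three pairwise coupling constants:
#' \code{C} (external site to opening), \code{D} (internal site to opening)
#' and \code{E} (between the two sites).
#'
#' A coupling above 1 means binding favors the coupled event; below 1 it
#' opposes it. With \code{C < 1} external protonation inhibits opening and
#' with \code{D > 1} internal protonation promotes it, which is the behaviour
#' the pH-gradient sensitivity of Hv1 channels requires.
#'
#' @param Kv0 Equilibrium constant of the closed-open transition at 0 mV (> 0).
#' @param q_g Gating charge of that transition, elementary charges (non-zero).
#' @param C Coupling of the external proton site to opening (> 0).
#' @param D Coupling of the internal proton site to opening (> 0).
#' @param E Coupling between the two proton sites (> 0).
#' @param pK_o Acid-dissociation exponent of the external site.
#' @param pK_i Acid-dissociation exponent of the internal site.
#' @param temperature_K Temperature in kelvin (> 0).
#' @return An object of class \code{"allosteric_params"} (a validated list).
#' @seealso [amhv1_gating_params()] for the published coral-channel preset.
#' @export
allosteric_params <- function(Kv0, q_g, C, D, E, pK_o, pK_i,
                              temperature_K = 295.15) {
  p <- list(Kv0 = Kv0, q_g = q_g, C = C, D = D, E = E,
            pK_o = pK_o, pK_i = pK_i, temperature_K = temperature_K)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("allosteric_params: '", nm, "' must be a finite numeric scalar")
  }
  if (Kv0 <= 0 || C <= 0 || D <= 0 || E <= 0)
    stop("allosteric_params: Kv0, C, D and E must be positive")
  if (q_g == 0) stop("allosteric_params: q_g must be non-zero")
  if (temperature_K <= 0) stop("allosteric_params: temperature_K must be positive")
  structure(p, class = "allosteric_params")
}

#' Published gating parameters of the coral AmHv1 channel model
#'
#' The parameter set that reproduces the model curve for the coral channel's
#' V0.5-vs-deltapH relation: E = 5e5, D = 1e5, C = 2e-4, Kv(0) = 5e-5,
#' q_g = 1.0 e0, pK_o = 3.4, pK_i = 7, at 22 degrees C.
#'
#' @param temperature_K Temperature in kelvin; default 295.15.
#' @return An \code{"allosteric_params"} object.
#' @export
amhv1_gating_params <- function(temperature_K = 295.15) {
  allosteric_params(Kv0 = 5e-5, q_g = 1.0, C = 2e-4, D = 1e5, E = 5e5,
                    pK_o = 3.4, pK_i = 7, temperature_K = temperature_K)
}

#' @export
print.allosteric_params <- function(x, ...) {
  cat("Allosteric gating parameters\n")
  cat(sprintf("  Kv(0) = %g, q_g = %g e0 (K(V) = Kv0*exp(q_g*V/VT))\n", x$Kv0, x$q_g))
  cat(sprintf("  couplings: C = %g (ext-open), D = %g (int-open), E = %g (ext-int)\n",
              x$C, x$D, x$E))
  cat(sprintf("  pK_o = %g, pK_i = %g, T = %g K (VT = %.3f mV)\n",
              x$pK_o, x$pK_i, x$temperature_K, thermal_voltage(x$temperature_K)))
  invisible(x)
}

#' Protonation weight of a single binding site
#'
#' Equilibrium weight of the protonated state of a single site relative to its
#' unprotonated state, \eqn{10^{pK - pH}}: 1 at pH = pK, 10 one pH unit below
#' the pK, and so on.
#'
#' @param pK Acid-dissociation exponent of the site.
#' @param pH pH of the solution facing the site.
#' @return Dimensionless bound:unbound weight. Vectorized over both arguments.
#' @export
binding_weight <- function(pK, pH) {
  stopifnot(is.numeric(pK), is.numeric(pH), all(is.finite(pK)), all(is.finite(pH)))
  10^(pK - pH)
}

# Log statistical weights of the 8 states, relative to the unbound closed
# state. Order: C, CHo, CHi, CHoHi, O, OHo, OHi, OHoHi. Computed in log space
# so the open-probability ratio stays finite at extreme voltages.
.log_state_weights <- function(params, V, pH_o, pH_i) {
  VT <- thermal_voltage(params$temperature_K)
  lxo <- (params$pK_o - pH_o) * log(10)
  lxi <- (params$pK_i - pH_i) * log(10)
  lK  <- log(params$Kv0) + params$q_g * V / VT
  lC <- log(params$C); lD <- log(params$D); lE <- log(params$E)
  rbind(
    C      = 0 * lK,
    CHo    = lxo + 0 * lK,
    CHi    = lxi + 0 * lK,
    CHoHi  = lE + lxo + lxi + 0 * lK,
    O      = lK,
    OHo    = lK + lC + lxo,
    OHi    = lK + lD + lxi,
    OHoHi  = lK + lC + lD + lE + lxo + lxi
  )
}

#' Statistical weights of the eight gating states
#'
#' Weights of the eight states of the allosteric scheme (closed/open times
#' unbound / externally protonated / internally protonated / doubly
#' protonated), relative to the unbound closed state, whose weight is exactly
#' 1. Couplings multiply a state's weight once per realized pairwise
#' interaction: \code{C} for open and externally bound, \code{D} for open and
#' internally bound, \code{E} for the two sites both occupied (in either
#' conformation). Detailed balance around every loop of the state graph holds
#' by construction because the weights are state functions.
#'
#' @param params An [allosteric_params()] object.
#' @param V Membrane potential in mV (scalar).
#' @param pH_o,pH_i External and internal pH.
#' @return Named numeric vector of 8 non-negative weights
#'   (\code{C, CHo, CHi, CHoHi, O, OHo, OHi, OHoHi}).
#' @export
state_weights <- function(params, V, pH_o, pH_i) {
  stopifnot(inherits(params, "allosteric_params"),
            is.numeric(V), length(V) == 1L, is.finite(V),
            is.finite(pH_o), is.finite(pH_i))
  lw <- .log_state_weights(params, V, pH_o, pH_i)
  w <- exp(drop(lw))
  names(w) <- rownames(lw)
  w
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Equilibrium open probability of the allosteric model
#'
#' Sum of the four open-state weights over the sum of all eight, evaluated in
#' log space so the result is well behaved at any finite voltage. Strictly
#' increasing in V and bounded in (0, 1).
#'
#' @inheritParams state_weights
#' @param V Membrane potential in mV; may be a vector.
#' @return Open probability, same length as \code{V}.
#' @export
open_probability <- function(params, V, pH_o, pH_i) {
  stopifnot(inherits(params, "allosteric_params"), is.numeric(V),
            is.finite(pH_o), is.finite(pH_i))
  vapply(V, function(v) {
    lw <- .log_state_weights(params, v, pH_o, pH_i)
    lopen <- .logsumexp(lw[5:8, 1])
    lclosed <- .logsumexp(lw[1:4, 1])
    # P = 1/(1 + closed/open)
    1 / (1 + exp(lclosed - lopen))
  }, numeric(1))
}

#' Half-activation voltage of the allosteric model
#'
#' Closed-form voltage at which the open probability is 1/2:
#' \deqn{V_{0.5} = (V_T/q_g)\,\ln\frac{1 + x_o + x_i + E x_o x_i}
#'   {K_V(0)(1 + C x_o + D x_i + C D E x_o x_i)}}
#' with \eqn{x_o = 10^{pK_o - pH_o}} and \eqn{x_i = 10^{pK_i - pH_i}}.
#'
#' @inheritParams state_weights
#' @return V0.5 in mV.
#' @export
solve_v_half <- function(params, pH_o, pH_i) {
  stopifnot(inherits(params, "allosteric_params"),
            all(is.finite(pH_o)), all(is.finite(pH_i)))
  if (params$q_g == 0) stop("solve_v_half: q_g must be non-zero")
  VT <- thermal_voltage(params$temperature_K)
  xo <- binding_weight(params$pK_o, pH_o)
  xi <- binding_weight(params$pK_i, pH_i)
  num <- 1 + xo + xi + params$E * xo * xi
  den <- params$Kv0 * (1 + params$C * xo + params$D * xi +
                         params$C * params$D * params$E * xo * xi)
  (VT / params$q_g) * log(num / den)
}

#' Threshold voltage of the allosteric model
#'
#' Voltage at which the open probability reaches a given fraction of its
#' saturating value (the V -> +Inf limit, which is 1). The default fraction of
#' 0.1 matches the threshold convention for conductance-voltage curves.
#'
#' @inheritParams state_weights
#' @param fraction Target open probability, strictly between 0 and 1.
#' @return Voltage in mV at which \code{open_probability == fraction}.
#' @export
solve_v_threshold <- function(params, pH_o, pH_i, fraction = 0.1) {
  stopifnot(inherits(params, "allosteric_params"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("solve_v_threshold: 'fraction' must lie strictly in (0, 1)")
  if (fraction == 0.5) return(solve_v_half(params, pH_o, pH_i))
  f <- function(v) open_probability(params, v, pH_o, pH_i) - fraction
  # bracket around V0.5, expanding until sign change
  v0 <- solve_v_half(params, pH_o, pH_i)
  half <- 10 * thermal_voltage(params$temperature_K) / abs(params$q_g)
  lo <- v0 - half; hi <- v0 + half
  for (k in 1:60) {
    if (f(lo) * f(hi) < 0) break
    lo <- lo - half; hi <- hi + half
  }
  if (f(lo) * f(hi) >= 0) stop("solve_v_threshold: could not bracket the root")
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Model V0.5 across a set of pH gradients
#'
#' Evaluates the closed-form half-activation voltage (and optionally the
#' threshold voltage) for each (pH_o, pH_i) pair, returning one row per pair.
#' With the coral parameter set the curve is sigmoidal in delta-pH: monotone
#' decreasing, saturating at both extremes because both proton sites titrate
#' fully.
#'
#' @param params An [allosteric_params()] object.
#' @param pH_o,pH_i Equal-length vectors of external and internal pH.
#' @param v_thr_fraction If non-NULL, also compute the threshold voltage at
#'   this fraction for each pair.
#' @return A data.frame with columns \code{pH_o}, \code{pH_i}, \code{delta_pH}
#'   (= pH_o - pH_i), \code{V_half_mV}, and \code{V_thr_mV} if requested.
#' @export
v_half_vs_delta_ph <- function(params, pH_o, pH_i, v_thr_fraction = NULL) {
  stopifnot(inherits(params, "allosteric_params"),
            length(pH_o) == length(pH_i), length(pH_o) >= 1L)
  out <- data.frame(
    pH_o = pH_o, pH_i = pH_i, delta_pH = pH_o - pH_i,
    V_half_mV = solve_v_half(params, pH_o, pH_i)
  )
  if (!is.null(v_thr_fraction)) {
    out$V_thr_mV <- mapply(function(po, pi_)
      solve_v_threshold(params, po, pi_, fraction = v_thr_fraction),
      pH_o, pH_i)
  }
  out
}
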