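#' Nernst reversal potential for protons
#'
#' \eqn{E_{rev} = \ln(10) V_T (pH_i - pH_o)} mV: about -58.6 mV per unit of
#' delta-pH (= pH_o - pH_i) at 22 C. Zero when there is no gradient, and
#' antisymmetric under exchange of the two sides.
#'
#' @param pH_o,pH_i External and internal pH.
#' @param temperature_K Temperature in kelvin.
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(pH_o, pH_i, temperature_K = 295.15) {
  stopifnot(temperature_K > 0)
  log(10) * thermal_voltage(temperature_K) * (pH_i - pH_o)
}

#' Reversal potential from an instantaneous tail I-V
#'
#' Finds the zero crossing of the instantaneous current-voltage relation by
#' linear interpolation between the bracketing points.
#'
#' @param iv Data frame with columns \code{V_mV} and \code{I_pA} (or a
#'   two-column table in that order).
#' @return Zero-crossing voltage in mV.
#' @export
reversal_from_tails <- function(iv) {
  iv <- as.data.frame(iv)
  if (!all(c("V_mV", "I_pA") %in% names(iv))) names(iv)[1:2] <- c("V_mV", "I_pA")
  iv <- iv[order(iv$V_mV), ]
  V <- iv$V_mV; I <- iv$I_pA
  if (any(I == 0)) return(V[which(I == 0)[1]])
  s <- which(I[-1] * I[-length(I)] < 0)
  if (length(s) == 0)
    stop("reversal_from_tails: current does not change sign over the voltage range")
  i <- s[1]
  V[i] - I[i] * (V[i + 1] - V[i]) / (I[i + 1] - I[i])
}

#' Conductance-voltage curve container
#'
#' @param V_mV Test potentials, mV.
#' @param G Conductance values (nS if raw, dimensionless if normalized).
#' @param sem Optional per-point standard errors, same scale as \code{G}.
#' @param normalized Logical: is \code{G} scaled to a maximum of ~1?
#' @return Object of class \code{"gv_curve"}.
#' @export
gv_curve <- function(V_mV, G, sem = NULL, normalized = FALSE) {
  stopifnot(length(V_mV) == length(G),
            is.null(sem) || length(sem) == length(G))
  if (normalized && any(G > 1 + 3 * (if (is.null(sem)) 0 else sem) + 1e-12))
    stop("gv_curve: normalized conductance exceeds 1 beyond its uncertainty")
  structure(list(V_mV = as.numeric(V_mV), G = as.numeric(G),
                 sem = if (is.null(sem)) NULL else as.numeric(sem),
                 normalized = normalized),
            class = "gv_curve")
}

#' @export
print.gv_curve <- function(x, ...) {
  cat(sprintf("G-V curve: %d points, %g..%g mV, %s%s\n", length(x$V_mV),
              min(x$V_mV), max(x$V_mV),
              if (x$normalized) "normalized" else "raw (nS)",
              if (!is.null(x$sem)) ", with sem" else ""))
  invisible(x)
}

#' @export
plot.gv_curve <- function(x, ...) {
  plot(x$V_mV, x$G, xlab = "V (mV)",
       ylab = if (x$normalized) "G/Gmax" else "G (nS)", pch = 16, ...)
  if (!is.null(x$sem))
    graphics::arrows(x$V_mV, x$G - x$sem, x$V_mV, x$G + x$sem,
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Conductance from steady-state currents
#'
#' Ohmic conversion \eqn{G(V) = I(V) / (V - V_{rev})} (pA/mV = nS). Voltages
#' closer to the reversal potential than the guard band are rejected because
#' the ratio is ill-conditioned there.
#'
#' @param iv Data frame with columns \code{V_mV}, \code{I_pA} (e.g. from
#'   [steady_state_currents()]), optionally \code{sem_pA}.
#' @param v_rev Reversal potential, mV.
#' @param normalize One of \code{"none"}, \code{"max"} (divide by the largest
#'   value) — normalization against a fitted G_max is done by
#'   [fit_boltzmann()] itself.
#' @param guard_mV Minimum allowed |V - v_rev|; default 1 mV.
#' @return A [gv_curve()].
#' @export
conductance_from_iv <- function(iv, v_rev, normalize = c("none", "max"),
                                guard_mV = 1) {
  normalize <- match.arg(normalize)
  iv <- as.data.frame(iv)
  if (!all(c("V_mV", "I_pA") %in% names(iv))) names(iv)[1:2] <- c("V_mV", "I_pA")
  dv <- iv$V_mV - v_rev
  if (any(abs(dv) < guard_mV))
    stop("conductance_from_iv: test potential within ", guard_mV,
         " mV of the reversal potential; drop it or adjust guard_mV")
  G <- iv$I_pA / dv
  sem <- if ("sem_pA" %in% names(iv)) iv$sem_pA / abs(dv) else NULL
  if (normalize == "max") {
    gmax <- max(G)
    gv_curve(iv$V_mV, G / gmax, sem = if (is.null(sem)) NULL else sem / gmax,
             normalized = TRUE)
  } else {
    gv_curve(iv$V_mV, G, sem = sem, normalized = FALSE)
  }
}

# shared nlsLM wrapper: optional weights, informative convergence error
.nls_fit <- function(formula, data, start, weights = NULL, lower = NULL,
                     what = "fit") {
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  # near-zero starts defeat the parameter-scaled numeric-derivative step
  start <- lapply(start, function(v) if (abs(v) < 1e-10) 0 else v)
  args <- list(formula, data = data, start = start, weights = quote(.w),
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(lower)) args$lower <- lower
  tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) stop(what, ": fit did not converge (",
                             conditionMessage(e), ")")
  )
}

#' Fit a Boltzmann function to a conductance-voltage curve
#'
#' Least-squares fit of
#' \deqn{G/G_{max} = \frac{1}{1 + \exp(-q (V - V_{0.5}) / V_T)}}
#' so that conductance rises with depolarization (q > 0). For a raw curve
#' G_max is fitted jointly, which avoids the bias of dividing by the largest
#' observed point when saturation is incomplete; for a normalized curve G_max
#' is held at 1. Points are weighted by 1/sem^2 when the curve carries
#' uncertainties.
#'
#' @param gv A [gv_curve()].
#' @param temperature_K Temperature, kelvin.
#' @return Object of class \code{"boltzmann_fit"} with elements
#'   \code{v_half} (mV), \code{q} (e0), \code{g_max}, \code{vcov},
#'   \code{temperature_K}, \code{fitted}, \code{residuals}.
#' @export
fit_boltzmann <- function(gv, temperature_K = 295.15) {
  stopifnot(inherits(gv, "gv_curve"))
  if (length(gv$V_mV) < 4) stop("fit_boltzmann: need at least 4 points")
  if (stats::sd(gv$G) < sqrt(.Machine$double.eps) * max(abs(gv$G), 1))
    stop("fit_boltzmann: conductance curve is flat")
  VT <- thermal_voltage(temperature_K)
  d <- data.frame(V = gv$V_mV, G = gv$G)
  w <- if (!is.null(gv$sem) && all(gv$sem > 0)) 1 / gv$sem^2 else NULL
  gmax0 <- max(d$G)
  vh0 <- d$V[which.min(abs(d$G / gmax0 - 0.5))]
  start <- list(q = 1.5, v_half = vh0)
  if (gv$normalized) {
    fit <- .nls_fit(G ~ 1 / (1 + exp(-q * (V - v_half) / VT)), d, start,
                    weights = w, what = "fit_boltzmann")
    gmax <- 1
  } else {
    start$g_max <- gmax0
    fit <- .nls_fit(G ~ g_max / (1 + exp(-q * (V - v_half) / VT)), d, start,
                    weights = w, what = "fit_boltzmann")
    gmax <- stats::coef(fit)[["g_max"]]
  }
  cf <- stats::coef(fit)
  structure(list(v_half = cf[["v_half"]], q = cf[["q"]], g_max = gmax,
                 vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 temperature_K = temperature_K,
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 nls = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else NULL
  cat(sprintf("Boltzmann G-V fit: V0.5 = %.4g mV, q = %.4g e0, Gmax = %.4g\n",
              x$v_half, x$q, x$g_max))
  if (!is.null(se))
    cat(sprintf("  se(V0.5) = %.3g mV, se(q) = %.3g e0\n",
                se[["v_half"]], se[["q"]]))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v_half = object$v_half, q = object$q, g_max = object$g_max)
}

#' Predict a Boltzmann G-V curve
#' @param object A \code{"boltzmann_fit"}.
#' @param V Voltages (mV) at which to evaluate.
#' @param ... Unused.
#' @return Conductance at \code{V} on the fitted scale.
#' @export
predict.boltzmann_fit <- function(object, V, ...) {
  VT <- thermal_voltage(object$temperature_K)
  object$g_max / (1 + exp(-object$q * (V - object$v_half) / VT))
}

#' Threshold voltage from the exponential foot of a G-V curve
#'
#' Fits the sub-maximal rising foot of the conductance-voltage relation to
#' \eqn{G(V) = G' \exp(q V / V_T)} and reports the apparent threshold
#' \eqn{V_{Thr} = (V_T / q) \ln(f\, G_{max} / G')}, the voltage at which the
#' fit reaches the fraction f (default 10%) of the maximal conductance. The
#' threshold is less sensitive than V0.5 to proton-depletion distortion of
#' the top of the curve.
#'
#' @param gv A [gv_curve()].
#' @param fraction Fraction of G_max defining the threshold (default 0.1).
#' @param foot_max Upper cutoff of the foot: only points with
#'   \code{G/Gmax <= foot_max} (default 0.3) enter the exponential fit.
#' @param g_max Maximal conductance on the same scale as \code{gv$G}; default
#'   1 for a normalized curve, otherwise the fitted G_max from
#'   [fit_boltzmann()].
#' @param temperature_K Temperature, kelvin.
#' @return Object of class \code{"threshold_fit"} with \code{g_prime},
#'   \code{q}, \code{v_thr}, \code{fraction}, \code{n_foot}.
#' @export
fit_threshold <- function(gv, fraction = 0.1, foot_max = 0.3, g_max = NULL,
                          temperature_K = 295.15) {
  stopifnot(inherits(gv, "gv_curve"), fraction > 0, fraction <= 1)
  VT <- thermal_voltage(temperature_K)
  if (is.null(g_max))
    g_max <- if (gv$normalized) 1 else fit_boltzmann(gv, temperature_K)$g_max
  keep <- gv$G > 0 & gv$G / g_max <= foot_max
  if (sum(keep) < 3)
    stop("fit_threshold: fewer than 3 points on the rising foot (G/Gmax <= ",
         foot_max, ")")
  d <- data.frame(V = gv$V_mV[keep], G = gv$G[keep])
  lmfit <- stats::lm(log(G) ~ V, data = d)
  start <- list(g_prime = exp(stats::coef(lmfit)[[1]]),
                q = stats::coef(lmfit)[[2]] * VT)
  fit <- .nls_fit(G ~ g_prime * exp(q * V / VT), d, start,
                  what = "fit_threshold")
  cf <- stats::coef(fit)
  v_thr <- (VT / cf[["q"]]) * log(fraction * g_max / cf[["g_prime"]])
  structure(list(g_prime = cf[["g_prime"]], q = cf[["q"]], v_thr = v_thr,
                 fraction = fraction, g_max = g_max, n_foot = sum(keep),
                 temperature_K = temperature_K),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential-foot fit: G' = %.4g, q = %.4g e0; V_Thr(%g%%) = %.4g mV (%d foot points)\n",
    x$g_prime, x$q, 100 * x$fraction, x$v_thr, x$n_foot))
  invisible(x)
}

#' Fit the exponential-with-delay activation time course
#'
#' Least-squares fit of \eqn{I(t) = I_{ss} (1 - e^{-(t-\delta)/\tau})} over a
#' window of the test pulse. The delay delta captures the sigmoidal onset of
#' a multi-state activation pathway; the window conventionally starts at the
#' second half of the pulse, so an estimated delay is an extrapolation of the
#' late time course and the fit records the window used.
#'
#' @param time_ms,current_pA The trace. \code{time_ms} is taken relative to
#'   the start of the test pulse.
#' @param window Two-element numeric \code{c(t_start, t_end)} in ms; default
#'   the second half of the trace.
#' @return Object of class \code{"activation_fit"} with \code{i_ss} (pA),
#'   \code{tau} (ms), \code{delta} (ms), \code{window}, \code{rms}.
#' @export
fit_activation_trace <- function(time_ms, current_pA, window = NULL) {
  stopifnot(length(time_ms) == length(current_pA), length(time_ms) >= 5)
  if (is.null(window)) window <- c(max(time_ms) / 2, max(time_ms))
  keep <- time_ms >= window[1] & time_ms <= window[2]
  if (sum(keep) < 4) stop("fit_activation_trace: window contains fewer than 4 samples")
  d <- data.frame(t = time_ms[keep], I = current_pA[keep])
  slope <- stats::coef(stats::lm(I ~ t, data = d))[[2]]
  if (slope < 0 && abs(slope) * diff(range(d$t)) > 0.05 * max(abs(d$I)))
    stop("fit_activation_trace: trace is decaying over the window; expected a rising current")
  # data-driven starts: plateau for I_ss, log-linearized approach for tau and
  # delta, with heuristic fallbacks — a window far past the rise leaves the
  # exponential poorly conditioned and sensitive to the starting point
  span <- diff(range(d$t))
  iss0 <- max(d$I) * 1.02 + 1e-9
  starts <- list()
  resid0 <- iss0 - d$I
  pos <- resid0 > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(resid0[pos]) ~ d$t[pos])
    sl <- stats::coef(lf)[[2]]
    if (is.finite(sl) && sl < 0 && -1 / sl < 20 * span) {
      tau0 <- -1 / sl
      starts <- list(list(i_ss = iss0, tau = tau0,
                          delta = max(0, tau0 * (stats::coef(lf)[[1]] -
                                                   log(iss0)))))
    }
  }
  starts <- c(starts,
              list(list(i_ss = iss0, tau = span / 3, delta = 0),
                   list(i_ss = iss0, tau = span / 10, delta = 0),
                   list(i_ss = iss0, tau = span, delta = min(d$t) / 2)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      .nls_fit(I ~ i_ss * (1 - exp(-(t - delta) / tau)), d, start = st,
               lower = c(i_ss = -Inf, tau = 1e-9, delta = 0),
               what = "fit_activation_trace"),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit_activation_trace: fit did not converge from any starting point")
  cf <- stats::coef(fit)
  structure(list(i_ss = cf[["i_ss"]], tau = cf[["tau"]], delta = cf[["delta"]],
                 window = window,
                 rms = sqrt(mean(stats::resid(fit)^2))),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf(
    "Activation fit: Iss = %.4g pA, tau = %.4g ms, delta = %.4g ms (window %g..%g ms, RMS %.3g pA)\n",
    x$i_ss, x$tau, x$delta, x$window[1], x$window[2], x$rms))
  invisible(x)
}

#' Voltage dependence of a kinetic parameter
#'
#' Fits \eqn{k(V) = k(0) e^{-V q_k / V_T}} to per-voltage values of the
#' activation time constant or delay. The default is a linear fit on
#' \code{log(k)}, which is robust and exact for noise-free exponential data;
#' a direct nonlinear fit on the linear scale is available.
#'
#' @param V_mV Voltages, mV.
#' @param k_ms Parameter values (tau or delta), ms; must be positive.
#' @param temperature_K Temperature, kelvin.
#' @param parameter Label: \code{"tau"} or \code{"delta"}.
#' @param method \code{"loglinear"} (default) or \code{"nls"}.
#' @return Object of class \code{"rate_voltage_fit"} with \code{k0} (ms) and
#'   \code{q_k} (e0).
#' @export
fit_rate_voltage <- function(V_mV, k_ms, temperature_K = 295.15,
                             parameter = c("tau", "delta"),
                             method = c("loglinear", "nls")) {
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  stopifnot(length(V_mV) == length(k_ms))
  if (length(V_mV) < 3) stop("fit_rate_voltage: need at least 3 voltages")
  if (any(k_ms <= 0)) stop("fit_rate_voltage: kinetic values must be positive")
  VT <- thermal_voltage(temperature_K)
  d <- data.frame(V = V_mV, k = k_ms)
  if (method == "loglinear") {
    lf <- stats::lm(log(k) ~ V, data = d)
    k0 <- exp(stats::coef(lf)[[1]])
    q_k <- -stats::coef(lf)[[2]] * VT
  } else {
    lf0 <- stats::lm(log(k) ~ V, data = d)
    fit <- .nls_fit(k ~ k0 * exp(-V * q_k / VT), d,
                    start = list(k0 = exp(stats::coef(lf0)[[1]]),
                                 q_k = -stats::coef(lf0)[[2]] * VT),
                    what = "fit_rate_voltage")
    k0 <- stats::coef(fit)[["k0"]]
    q_k <- stats::coef(fit)[["q_k"]]
  }
  structure(list(k0 = k0, q_k = q_k, parameter = parameter, method = method,
                 temperature_K = temperature_K),
            class = "rate_voltage_fit")
}

#' @export
print.rate_voltage_fit <- function(x, ...) {
  cat(sprintf("Rate-voltage fit (%s, %s): %s(0) = %.4g ms, q = %.4g e0\n",
              x$parameter, x$method, x$parameter, x$k0, x$q_k))
  invisible(x)
}

#' p/4 leak subtraction
#'
#' Removes the linear (leak) current from every trace using its attached
#' subsweeps: each test pulse of amplitude (V_test - V_hold) is accompanied by
#' N sub-threshold pulses of amplitude (V_test - V_hold)/N, whose responses
#' are purely linear; the corrected trace is
#' \code{raw - N * mean(subsweep responses)}. A purely ohmic cell yields
#' identically zero output.
#'
#' Using a single full-amplitude subsweep (N = 1) from a holding level where
#' channels open subtracts the channel current along with the leak; the
#' function warns about this misuse.
#'
#' @param family A [current_family()] carrying subsweeps.
#' @return The corrected [current_family()], with subsweeps dropped and
#'   \code{extra$leak_subtracted = TRUE}.
#' @export
p4_leak_subtract <- function(family) {
  stopifnot(inherits(family, "current_family"))
  if (is.null(family$subsweeps))
    stop("p4_leak_subtract: family carries no subsweeps")
  n <- family$protocol$p4_n
  if (n < 1) stop("p4_leak_subtract: protocol declares no subsweeps")
  if (n == 1)
    warning("p4_leak_subtract: N = 1 full-amplitude subsweep subtracts the ",
            "channel current together with the leak")
  corrected <- family$traces
  for (j in seq_len(ncol(corrected))) {
    corrected[, j] <- corrected[, j] -
      n * rowMeans(family$subsweeps[[j]])
  }
  out <- family
  out$traces <- corrected
  out$subsweeps <- NULL
  out$extra$leak_subtracted <- TRUE
  out
}
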