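#' Fraction of current blocked
#'
#' \eqn{F_B = 1 - I_{blocker}/I_{control}}: 0 for no block, 1 for complete
#' block. Values outside [0, 1] (from noise) are retained — clipping them
#' before fitting would bias the estimates — but a warning flags them; use
#' \code{clip = TRUE} for reporting.
#'
#' @param I_control,I_blocker Currents (pA) at the same voltage and protocol,
#'   before and during blocker application. Vectorized.
#' @param clip Clip the result into [0, 1]?
#' @return Fraction blocked.
#' @export
fraction_blocked <- function(I_control, I_blocker, clip = FALSE) {
  stopifnot(length(I_control) == length(I_blocker))
  if (any(I_control == 0)) stop("fraction_blocked: zero control current")
  fb <- 1 - I_blocker / I_control
  if (any(fb < 0 | fb > 1))
    warning("fraction_blocked: values outside [0, 1]; noise or run-down?")
  if (clip) fb <- pmin(pmax(fb, 0), 1)
  fb
}

#' Woodhull voltage-dependent block
#'
#' Fraction blocked by a charged blocker binding at an electrical distance
#' delta into the membrane field:
#' \deqn{F_B(V) = \frac{1}{1 + \exp(-\delta z (V - V_{0.5}) / V_T)}}
#' Block deepens with depolarization when \eqn{\delta z > 0}; at
#' \eqn{V = V_{0.5}} half the current is blocked.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param delta Fraction of the electric field at the binding site, in [0, 1].
#' @param z Blocker valence (2 for zinc).
#' @param v_half Voltage of half block, mV.
#' @param temperature_K Temperature, kelvin.
#' @return Fraction blocked in (0, 1).
#' @export
woodhull_fraction <- function(V, delta, z, v_half, temperature_K = 295.15) {
  stopifnot(delta >= 0, delta <= 1)
  VT <- thermal_voltage(temperature_K)
  1 / (1 + exp(-delta * z * (V - v_half) / VT))
}

#' Fit the Woodhull block model
#'
#' Least-squares estimates of the electrical distance delta and the half-block
#' voltage, with the blocker valence held fixed (zinc is divalent, z = 2).
#' delta and z enter the model only through their product — the effective
#' blocking charge \eqn{z\delta} — so z cannot be co-estimated; the fit
#' reports \code{z_delta} alongside the fixed-z decomposition.
#'
#' Internally the logistic is fitted in its linear parametrization
#' \eqn{F_B = 1/(1 + e^{-(a + bV)})}, which stays well-conditioned even for
#' voltage-independent block (b -> 0, where the half-block voltage is
#' undefined and reported as NA); delta = b V_T / z and V_0.5 = -a/b.
#'
#' @param data Data frame with columns \code{V_mV} and \code{F_B} (or a
#'   two-column table in that order).
#' @param z Blocker valence, fixed during the fit.
#' @param temperature_K Temperature, kelvin.
#' @return Object of class \code{"woodhull_fit"} with \code{delta},
#'   \code{v_half} (mV), \code{z} (fixed), \code{z_delta} (effective charge),
#'   \code{vcov} (covariance of delta and v_half, by the delta method).
#' @export
fit_woodhull <- function(data, z = 2, temperature_K = 295.15) {
  d <- as.data.frame(data)
  if (!all(c("V_mV", "F_B") %in% names(d))) names(d)[1:2] <- c("V_mV", "F_B")
  if (nrow(d) < 4) stop("fit_woodhull: need at least 4 voltages")
  stopifnot(z > 0)
  VT <- thermal_voltage(temperature_K)
  dd <- data.frame(V = d$V_mV, FB = d$F_B)
  # logit-linear starting values on clamped fractions
  fb0 <- pmin(pmax(dd$FB, 1e-4), 1 - 1e-4)
  st <- stats::coef(stats::lm(log(fb0 / (1 - fb0)) ~ dd$V))
  fit <- .nls_fit(FB ~ 1 / (1 + exp(-(a + b * V))), dd,
                  start = list(a = st[[1]], b = st[[2]]),
                  what = "fit_woodhull")
  cf <- stats::coef(fit)
  a <- cf[["a"]]; b <- cf[["b"]]
  delta <- b * VT / z
  v_half <- if (abs(b) > 1e-10) -a / b else NA_real_
  if (delta < 0) {
    warning("fit_woodhull: block decreases with depolarization; delta clipped at 0")
    delta <- 0
  }
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  vcov_out <- NULL
  if (!is.null(vc) && is.finite(v_half)) {
    J <- rbind(delta = c(0, VT / z),
               v_half = c(-1 / b, a / b^2))
    vcov_out <- J %*% vc %*% t(J)
    dimnames(vcov_out) <- list(c("delta", "v_half"), c("delta", "v_half"))
  }
  structure(list(delta = delta, v_half = v_half, z = z,
                 z_delta = b * VT, vcov = vcov_out,
                 temperature_K = temperature_K),
            class = "woodhull_fit")
}

#' @export
print.woodhull_fit <- function(x, ...) {
  cat(sprintf(
    "Woodhull block fit: delta = %.3g, V0.5 = %.4g mV (z = %g fixed, z*delta = %.3g)\n",
    x$delta, x$v_half, x$z, x$z_delta))
  invisible(x)
}

#' @export
coef.woodhull_fit <- function(object, ...) {
  c(delta = object$delta, v_half = object$v_half, z = object$z)
}

#' Hill dose-response for block
#'
#' \eqn{F_B = 1 / (1 + (K_D / [B])^{n_H})}: half block at the apparent
#' dissociation constant, complete block at saturating concentration.
#'
#' @param conc Blocker concentration, uM (vectorized, positive).
#' @param KD Apparent dissociation constant, uM.
#' @param n Hill coefficient.
#' @return Fraction blocked.
#' @export
hill_fraction <- function(conc, KD, n) {
  if (any(conc <= 0)) stop("hill_fraction: concentration must be positive")
  stopifnot(KD > 0, n > 0)
  1 / (1 + (KD / conc)^n)
}

#' Fit the Hill dose-response
#'
#' Least-squares estimates of the apparent K_D and Hill coefficient on the
#' linear fraction-blocked scale, with concentrations ideally log-spaced over
#' at least two decades.
#'
#' @param data Data frame with columns \code{conc_uM} and \code{F_B} (or a
#'   two-column table in that order).
#' @return Object of class \code{"hill_fit"} with \code{KD} (uM), \code{n},
#'   \code{vcov}.
#' @export
fit_hill <- function(data) {
  d <- as.data.frame(data)
  if (!all(c("conc_uM", "F_B") %in% names(d))) names(d)[1:2] <- c("conc_uM", "F_B")
  if (nrow(d) < 4) stop("fit_hill: need at least 4 concentrations")
  if (length(unique(d$conc_uM)) < 2)
    stop("fit_hill: degenerate input — a single concentration cannot identify KD and n")
  if (any(d$conc_uM <= 0)) stop("fit_hill: concentrations must be positive")
  dd <- data.frame(conc = d$conc_uM, FB = d$F_B)
  kd0 <- exp(stats::approx(dd$FB, log(dd$conc), xout = 0.5, ties = mean,
                           rule = 2)$y)
  fit <- .nls_fit(FB ~ 1 / (1 + (KD / conc)^n), dd,
                  start = list(KD = kd0, n = 1),
                  lower = c(KD = 1e-12, n = 1e-6),
                  what = "fit_hill")
  cf <- stats::coef(fit)
  structure(list(KD = cf[["KD"]], n = cf[["n"]],
                 vcov = tryCatch(stats::vcov(fit), error = function(e) NULL)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dose-response fit: KD = %.4g uM, n = %.3g\n", x$KD, x$n))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(KD = object$KD, n = object$n)
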