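#' Voltage-clamp step protocol
#'
#' Describes a family of depolarizing test pulses from a holding potential,
#' with optional tail step and optional p/4 leak-subtraction subsweeps.
#'
#' @param holding_mV Holding potential, mV.
#' @param test_mV Vector of unique test potentials, mV.
#' @param duration_ms Test-pulse duration, ms.
#' @param dt_ms Sampling interval, ms.
#' @param tail_mV Optional tail (repolarization) potential, mV.
#' @param p4_n Number of leak subsweeps per test pulse (0 = none; the usual
#'   protocol uses 4).
#' @param p4_holding_mV Sub-threshold holding level the subsweeps start from;
#'   defaults to \code{holding_mV}.
#' @return An object of class \code{"voltage_protocol"}.
#' @export
voltage_protocol <- function(holding_mV, test_mV, duration_ms, dt_ms,
                             tail_mV = NULL, p4_n = 0L,
                             p4_holding_mV = holding_mV) {
  stopifnot(is.numeric(holding_mV), length(holding_mV) == 1L,
            is.numeric(test_mV), length(test_mV) >= 1L,
            is.numeric(duration_ms), duration_ms > 0,
            is.numeric(dt_ms), dt_ms > 0,
            p4_n >= 0)
  if (anyDuplicated(test_mV)) stop("voltage_protocol: test potentials must be unique")
  structure(list(holding_mV = holding_mV, test_mV = as.numeric(test_mV),
                 duration_ms = duration_ms, dt_ms = dt_ms,
                 tail_mV = tail_mV, p4_n = as.integer(p4_n),
                 p4_holding_mV = p4_holding_mV),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol: hold %g mV; %d test pulses %g..%g mV; %g ms @ %g ms\n",
              x$holding_mV, length(x$test_mV), min(x$test_mV), max(x$test_mV),
              x$duration_ms, x$dt_ms))
  if (!is.null(x$tail_mV)) cat(sprintf("  tail potential %g mV\n", x$tail_mV))
  if (x$p4_n > 0) cat(sprintf("  p/%d subsweeps from %g mV\n", x$p4_n, x$p4_holding_mV))
  invisible(x)
}

#' A family of current traces indexed by test potential
#'
#' Container for a set of current records on a shared time base, one trace per
#' test potential, with the recording metadata the downstream fits need.
#'
#' @param time_ms Strictly increasing time base, ms.
#' @param traces Numeric matrix, one column per test potential (pA); column
#'   order matches \code{protocol$test_mV}.
#' @param protocol A [voltage_protocol()].
#' @param pH_o,pH_i External and internal pH of the recording.
#' @param temperature_K Temperature, kelvin.
#' @param configuration Recording configuration label: \code{"whole-cell"},
#'   \code{"inside-out"} or \code{"outside-out"}.
#' @param subsweeps Optional list (one element per test potential) of matrices
#'   holding the p/4 subsweep responses (pA), same time base.
#' @param extra Optional named list of extra metadata (e.g. generator seed).
#' @return An object of class \code{"current_family"}.
#' @export
current_family <- function(time_ms, traces, protocol, pH_o, pH_i,
                           temperature_K = 295.15,
                           configuration = "whole-cell",
                           subsweeps = NULL, extra = list()) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  traces <- as.matrix(traces)
  if (length(time_ms) != nrow(traces))
    stop("current_family: traces must have one row per time point")
  if (any(diff(time_ms) <= 0))
    stop("current_family: time base must be strictly increasing")
  if (ncol(traces) != length(protocol$test_mV))
    stop("current_family: need one trace per test potential")
  colnames(traces) <- format(protocol$test_mV, trim = TRUE)
  configuration <- match.arg(configuration,
                             c("whole-cell", "inside-out", "outside-out"))
  if (!is.null(subsweeps)) {
    if (length(subsweeps) != length(protocol$test_mV))
      stop("current_family: need one subsweep set per test potential")
    if (any(vapply(subsweeps, nrow, 1L) != length(time_ms)))
      stop("current_family: subsweeps must share the trace time base")
  }
  structure(list(time_ms = as.numeric(time_ms), traces = traces,
                 protocol = protocol, pH_o = pH_o, pH_i = pH_i,
                 temperature_K = temperature_K,
                 configuration = configuration,
                 subsweeps = subsweeps, extra = extra),
            class = "current_family")
}

#' @export
print.current_family <- function(x, ...) {
  cat(sprintf("Current family (%s): %d traces x %d samples, pH_o %g / pH_i %g (dpH %g)\n",
              x$configuration, ncol(x$traces), nrow(x$traces),
              x$pH_o, x$pH_i, x$pH_o - x$pH_i))
  cat(sprintf("  test potentials %g..%g mV, %g ms pulses, T = %g K%s\n",
              min(x$protocol$test_mV), max(x$protocol$test_mV),
              x$protocol$duration_ms, x$temperature_K,
              if (!is.null(x$subsweeps)) sprintf(", p/%d subsweeps attached",
                                                 x$protocol$p4_n) else ""))
  invisible(x)
}

#' Steady-state current per test potential
#'
#' Averages the final stretch of each trace, where the current has settled.
#'
#' @param family A [current_family()].
#' @param tail_fraction Fraction of the pulse (from the end) to average over.
#' @return Data frame with columns \code{V_mV} and \code{I_pA}.
#' @export
steady_state_currents <- function(family, tail_fraction = 0.1) {
  stopifnot(inherits(family, "current_family"),
            tail_fraction > 0, tail_fraction <= 1)
  n <- nrow(family$traces)
  idx <- seq.int(max(1L, ceiling(n * (1 - tail_fraction))), n)
  data.frame(V_mV = family$protocol$test_mV,
             I_pA = colMeans(family$traces[idx, , drop = FALSE]))
}

#' Instantaneous current-voltage relation from a tail family
#'
#' Reads the current at (or immediately after) the step to each tail
#' potential, giving the instantaneous I-V whose zero crossing is the reversal
#' potential.
#'
#' @param family A tail-current [current_family()] whose traces start at the
#'   moment of the step to the tail potential.
#' @param t_ms Time after the step at which to read the current; default the
#'   first sample.
#' @return Data frame with columns \code{V_mV} and \code{I_pA}.
#' @export
instantaneous_iv <- function(family, t_ms = NULL) {
  stopifnot(inherits(family, "current_family"))
  i <- if (is.null(t_ms)) 1L else which.min(abs(family$time_ms - t_ms))
  data.frame(V_mV = family$protocol$test_mV,
             I_pA = as.numeric(family$traces[i, ]))
}
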