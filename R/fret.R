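#' Apparent FRET efficiency under random dimer assembly
#'
#' Donor- and acceptor-tagged subunits assembling at random into dimers give a
#' donor an acceptor partner with probability \eqn{f_A = 1/(1 + \rho\, r)},
#' where r is the donor/acceptor intensity ratio and rho the
#' acceptor-to-donor brightness ratio. The measured apparent efficiency is
#' then \eqn{E_{app} = E_{max} f_A}: it approaches the pairwise efficiency
#' E_max in acceptor-dominated cells (r -> 0) and vanishes as r -> Inf.
#'
#' @param ratio Donor/acceptor intensity ratio I_d/I_a (>= 0, vectorized).
#' @param e_max Pairwise FRET efficiency of one donor-acceptor pair, (0, 1).
#' @param rho Acceptor-to-donor brightness ratio (> 0).
#' @return Apparent FRET efficiency.
#' @export
dimer_eapp <- function(ratio, e_max, rho) {
  if (any(ratio < 0)) stop("dimer_eapp: ratio must be non-negative")
  stopifnot(e_max > 0, e_max < 1, rho > 0)
  e_max / (1 + rho * ratio)
}

#' Fit the random-assembly dimer FRET model
#'
#' Bins per-cell apparent FRET efficiencies into donor/acceptor ratio windows,
#' averages each bin (mean and sem), and least-squares fits the dimer model
#' [dimer_eapp()] for the pairwise efficiency E_max and brightness ratio rho.
#'
#' Bins are weighted by their occupancy so that sparse tail bins do not
#' dominate; with \code{bin_width = NULL} the model is fitted to the
#' per-cell points directly (no binning), which recovers noise-free
#' populations exactly.
#'
#' @param samples Data frame with columns \code{I_d}, \code{I_a},
#'   \code{E_app} (one row per cell).
#' @param bin_width Ratio window width for binning; default 0.1. \code{NULL}
#'   fits per cell without binning.
#' @param R0 Optional Forster radius (Angstrom); if supplied the fit also
#'   reports the implied donor-acceptor distance [forster_distance()].
#' @return Object of class \code{"dimer_fret_fit"} with \code{e_max},
#'   \code{rho}, \code{binned} (the bin table), \code{R0},
#'   \code{distance_A} (if R0 given), \code{n_cells}.
#' @export
fit_dimer_model <- function(samples, bin_width = 0.1, R0 = NULL) {
  d <- as.data.frame(samples)
  stopifnot(all(c("I_d", "I_a", "E_app") %in% names(d)))
  if (nrow(d) < 10) stop("fit_dimer_model: need at least 10 cells")
  if (any(d$I_a <= 0)) stop("fit_dimer_model: acceptor intensity must be positive")
  ratio <- d$I_d / d$I_a
  if (is.null(bin_width)) {
    agg <- data.frame(ratio = ratio, E_app = d$E_app, sem = NA_real_, n = 1L)
  } else {
    bin <- floor(ratio / bin_width)
    agg <- do.call(rbind, lapply(split(data.frame(ratio, E = d$E_app), bin),
                                 function(g) data.frame(
                                   ratio = mean(g$ratio),
                                   E_app = mean(g$E),
                                   sem = if (nrow(g) > 1)
                                     stats::sd(g$E) / sqrt(nrow(g)) else NA_real_,
                                   n = nrow(g))))
    if (nrow(agg) < 3) stop("fit_dimer_model: fewer than 3 occupied ratio bins")
  }
  fit <- .nls_fit(E_app ~ e_max / (1 + rho * ratio), agg,
                  start = list(e_max = max(agg$E_app), rho = 1),
                  weights = agg$n,
                  lower = c(e_max = 0, rho = 1e-9),
                  what = "fit_dimer_model")
  cf <- stats::coef(fit)
  out <- list(e_max = cf[["e_max"]], rho = cf[["rho"]], binned = agg,
              R0 = R0, n_cells = nrow(d),
              vcov = tryCatch(stats::vcov(fit), error = function(e) NULL))
  if (!is.null(R0) && out$e_max > 0 && out$e_max < 1)
    out$distance_A <- forster_distance(out$e_max, R0)
  structure(out, class = "dimer_fret_fit")
}

#' @export
print.dimer_fret_fit <- function(x, ...) {
  cat(sprintf("Dimer FRET fit (%d cells, %d bins): E_max = %.3g, rho = %.3g\n",
              x$n_cells, nrow(x$binned), x$e_max, x$rho))
  if (!is.null(x$distance_A))
    cat(sprintf("  fluorophore separation %.3g A (R0 = %g A)\n",
                x$distance_A, x$R0))
  invisible(x)
}

#' Donor-acceptor distance from pairwise FRET efficiency
#'
#' Inverts the Forster relation: \eqn{R = R_0 (1/E - 1)^{1/6}}. E = 0.5 gives
#' R = R0 by definition of the Forster radius.
#'
#' @param E Pairwise FRET efficiency, strictly in (0, 1).
#' @param R0 Forster radius, Angstrom.
#' @return Distance in Angstrom.
#' @seealso [fret_from_distance()] for the inverse.
#' @export
forster_distance <- function(E, R0) {
  if (any(E <= 0 | E >= 1)) stop("forster_distance: E must lie strictly in (0, 1)")
  stopifnot(R0 > 0)
  R0 * (1 / E - 1)^(1 / 6)
}

#' Pairwise FRET efficiency at a given distance
#'
#' \eqn{E = 1 / (1 + (R/R_0)^6)}, the inverse of [forster_distance()].
#'
#' @param R Donor-acceptor distance, Angstrom (> 0).
#' @param R0 Forster radius, Angstrom.
#' @return Efficiency in (0, 1).
#' @export
fret_from_distance <- function(R, R0) {
  stopifnot(all(R > 0), R0 > 0)
  1 / (1 + (R / R0)^6)
}
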