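test_that("Nernst potential is linear and antisymmetric in the pH gradient", {
  expect_equal(nernst_potential(7, 7), 0)
  expect_equal(nernst_potential(7, 6), -58.5639, tolerance = 1e-5)
  expect_equal(nernst_potential(6, 7), -nernst_potential(7, 6))
  dpH <- seq(-3, 3, by = 0.5)
  e <- nernst_potential(7, 7 - dpH)
  slope <- diff(e) / diff(dpH)
  expect_equal(slope, rep(-log(10) * thermal_voltage(), length(slope)),
               tolerance = 1e-12)
})

test_that("tail-current reversal interpolates the zero crossing", {
  expect_equal(reversal_from_tails(data.frame(V_mV = c(-70, -50),
                                              I_pA = c(-1, 1))), -60)
  expect_error(reversal_from_tails(data.frame(V_mV = c(-70, -50),
                                              I_pA = c(1, 2))), "sign")
  fam <- generate_tail_family(seq(-100, -20, 10), prepulse_mV = 60,
                              gating = list(v_half = 7.85, q = 2.09),
                              pH_o = 7, pH_i = 6, noise_sd_pA = 0.5, seed = 5)
  expect_equal(reversal_from_tails(instantaneous_iv(fam)),
               nernst_potential(7, 6), tolerance = 0.5 / 58.6)
})

test_that("ohmic conductance conversion and its guard band", {
  g <- conductance_from_iv(data.frame(V_mV = 0, I_pA = 2), v_rev = -50,
                           guard_mV = 0.5)
  expect_equal(g$G, 0.04)
  expect_error(conductance_from_iv(data.frame(V_mV = -50, I_pA = 0), -50),
               "guard|reversal")
  # round trip: Boltzmann-generated currents return the generating curve
  V <- seq(-40, 80, 10)
  gg <- boltzmann_g(V, 10, 2)
  iv <- data.frame(V_mV = V, I_pA = 3 * gg * (V - (-58.6)))
  gv <- conductance_from_iv(iv, -58.6)
  expect_equal(gv$G / 3, gg, tolerance = 1e-12)
})

test_that("Boltzmann fit recovers published G-V parameter sets exactly", {
  V <- seq(-50, 60, 10)
  for (ref in list(fig_gv, fig_gv_h_long)) {
    gv <- gv_curve(V, boltzmann_g(V, ref$v_half, ref$q), normalized = TRUE)
    f <- fit_boltzmann(gv)
    expect_equal(f$v_half, ref$v_half, tolerance = 1e-4)
    expect_equal(f$q, ref$q, tolerance = 1e-4)
    # midpoint identity of the fitted curve
    expect_equal(predict(f, f$v_half), f$g_max / 2, tolerance = 1e-12)
  }
  # unnormalized route fits G_max jointly
  gvr <- gv_curve(V, 4.2 * boltzmann_g(V, fig_gv$v_half, fig_gv$q))
  fr <- fit_boltzmann(gvr)
  expect_equal(fr$g_max, 4.2, tolerance = 1e-6)
  expect_equal(fr$v_half, fig_gv$v_half, tolerance = 1e-6)
})

test_that("Boltzmann fit is unbiased under measurement noise", {
  V <- seq(-50, 60, 10)
  g0 <- boltzmann_g(V, fig_gv$v_half, fig_gv$q)
  set.seed(101)
  est <- t(replicate(200, {
    f <- fit_boltzmann(gv_curve(V, g0 + rnorm(length(V), 0, 0.03)))
    c(f$v_half, f$q)
  }))
  expect_lt(abs(mean(est[, 1]) - fig_gv$v_half) / abs(fig_gv$v_half), 0.02)
  expect_lt(abs(mean(est[, 2]) - fig_gv$q) / fig_gv$q, 0.02)
})

test_that("Boltzmann fit rejects degenerate input", {
  expect_error(fit_boltzmann(gv_curve(1:3, c(0.1, 0.5, 0.9))), "4 points")
  expect_error(fit_boltzmann(gv_curve(seq(-50, 60, 10), rep(0.5, 12))), "flat")
})

test_that("threshold fit matches the closed form on an exact exponential foot", {
  VT <- thermal_voltage()
  V <- seq(-50, 60, 10)
  g_prime <- 1e-3; q <- 2
  gexp <- g_prime * exp(q * V / VT)
  tf <- fit_threshold(gv_curve(V, pmin(gexp, 1)), g_max = 1)
  expect_equal(tf$v_thr, (VT / q) * log(0.1 / g_prime), tolerance = 1e-9)
  # fraction = 1 with G' = G_max puts the threshold at 0 mV
  tf1 <- fit_threshold(gv_curve(V, pmin(exp(q * V / VT), 1)), fraction = 1,
                       g_max = 1)
  expect_equal(tf1$v_thr, 0, tolerance = 1e-9)
})

test_that("threshold sits below V0.5 on a Boltzmann foot", {
  V <- seq(-60, 60, 5)
  gv <- gv_curve(V, boltzmann_g(V, fig_gv$v_half, fig_gv$q), normalized = TRUE)
  tf <- fit_threshold(gv)
  expect_lt(tf$v_thr, fig_gv$v_half)
  expect_gte(tf$n_foot, 3)
  expect_error(fit_threshold(gv_curve(c(0, 10, 20), boltzmann_g(c(0, 10, 20), -50, 2),
                                      normalized = TRUE)), "foot")
})

test_that("activation fit recovers the exponential-with-delay parameters", {
  tt <- seq(1, 500, by = 1)
  tr <- ifelse(tt > 10, 100 * (1 - exp(-(tt - 10) / 50)), 0)
  f <- fit_activation_trace(tt, tr)
  expect_equal(f$i_ss, 100, tolerance = 1e-6)
  expect_equal(f$tau, 50, tolerance = 1e-6)
  expect_equal(f$delta, 10, tolerance = 1e-5)
  expect_equal(f$window, c(250, 500))
  # delta = 0 reduces to a mono-exponential
  tr0 <- 100 * (1 - exp(-tt / 50))
  f0 <- fit_activation_trace(tt, tr0)
  expect_equal(f0$delta, 0, tolerance = 1e-4)
  # decaying trace is rejected
  expect_error(fit_activation_trace(tt, 100 * exp(-tt / 50)), "decay")
})

test_that("activation tau is recovered within 5% under trace noise", {
  tt <- seq(1, 500, by = 1)
  tr <- ifelse(tt > 10, 100 * (1 - exp(-(tt - 10) / 50)), 0)
  set.seed(202)
  taus <- replicate(100, fit_activation_trace(tt, tr + rnorm(length(tt), 0, 2),
                                              window = c(20, 500))$tau)
  expect_lt(abs(mean(taus) - 50) / 50, 0.05)
  # fitted delay stays below fitted tau when generated with delta < tau
  dels <- replicate(20, {
    f <- fit_activation_trace(tt, tr + rnorm(length(tt), 0, 2), window = c(20, 500))
    f$delta < f$tau
  })
  expect_true(all(dels))
})

test_that("rate-voltage fit recovers the published kinetic parameters", {
  V <- seq(0, 120, 10)
  VT <- thermal_voltage()
  ftau <- fit_rate_voltage(V, fig_kin$tau0 * exp(-V * fig_kin$q_tau / VT),
                           parameter = "tau")
  expect_equal(ftau$k0, fig_kin$tau0, tolerance = 1e-9)
  expect_equal(ftau$q_k, fig_kin$q_tau, tolerance = 1e-9)
  fdel <- fit_rate_voltage(V, fig_kin$delta0 * exp(-V * fig_kin$q_delta / VT),
                           parameter = "delta")
  expect_equal(fdel$k0, fig_kin$delta0, tolerance = 1e-9)
  expect_equal(fdel$q_k, fig_kin$q_delta, tolerance = 1e-9)
  # nls route agrees with the log-linear route on clean data
  fnls <- fit_rate_voltage(V, fig_kin$tau0 * exp(-V * fig_kin$q_tau / VT),
                           method = "nls")
  expect_equal(fnls$k0, fig_kin$tau0, tolerance = 1e-6)
  # voltage-independent values give zero charge
  expect_equal(fit_rate_voltage(V, rep(30, length(V)))$q_k, 0, tolerance = 1e-12)
  expect_error(fit_rate_voltage(V, rep(-1, length(V))), "positive")
})

test_that("p/4 subtraction removes exactly the linear component", {
  pr <- voltage_protocol(-60, seq(-50, 60, 10), 500, 1, p4_n = 4,
                         p4_holding_mV = -80)
  bolt <- list(v_half = 7.85, q = 2.09)
  leak_only <- generate_current_family(pr, bolt, 7, 6, g_max_nS = 0,
                                       g_leak_nS = 3)
  expect_equal(max(abs(p4_leak_subtract(leak_only)$traces)), 0,
               tolerance = 1e-12)
  both <- generate_current_family(pr, bolt, 7, 6, g_max_nS = 5, g_leak_nS = 2)
  chan_only <- generate_current_family(pr, bolt, 7, 6, g_max_nS = 5,
                                       g_leak_nS = 0)
  corrected <- p4_leak_subtract(both)
  expect_lt(max(abs(corrected$traces - chan_only$traces)), 1e-9)
  expect_true(isTRUE(corrected$extra$leak_subtracted))
  expect_null(corrected$subsweeps)
  # N = 1 misuse warns
  pr1 <- voltage_protocol(-60, seq(-50, 60, 10), 500, 1, p4_n = 1)
  f1 <- generate_current_family(pr1, bolt, 7, 6, g_leak_nS = 1)
  expect_warning(p4_leak_subtract(f1), "channel current")
  prn <- voltage_protocol(-60, seq(-50, 60, 10), 500, 1)  # no subsweeps
  no_p4 <- generate_current_family(prn, bolt, 7, 6, g_leak_nS = 1)
  expect_error(p4_leak_subtract(no_p4), "subsweeps")
})
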