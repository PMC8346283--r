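test_that("binding weight is the titration ratio 10^(pK - pH)", {
  expect_equal(binding_weight(7, 7), 1)
  expect_equal(binding_weight(7, 6), 10)
  expect_equal(binding_weight(3.4, 7), 10^(-3.6))
})

test_that("state weights follow the coupled-sites construction", {
  p <- amhv1_gating_params()
  w <- state_weights(p, 0, 7, 7)
  expect_named(w, c("C", "CHo", "CHi", "CHoHi", "O", "OHo", "OHi", "OHoHi"))
  expect_identical(w[["C"]], 1)
  expect_true(all(w >= 0) && all(is.finite(w)))
  # frozen oracle values: explicit enumeration at V = 0, pH_o = pH_i = 7
  expect_equal(sum(w[1:4]), 127.5945728, tolerance = 1e-8)
  expect_equal(sum(w[5:8]), 5.1256443, tolerance = 1e-7)

  # neutral couplings: open and closed tiers share the same binding factors
  pn <- allosteric_params(Kv0 = 0.01, q_g = 1, C = 1, D = 1, E = 1,
                          pK_o = 5, pK_i = 7)
  wn <- state_weights(pn, 30, 6, 6.5)
  K <- wn[["O"]]
  expect_equal(unname(wn[5:8] / K), unname(wn[1:4]), tolerance = 1e-12)

  # far above both pKs only the unbound states carry weight
  wfar <- state_weights(p, 0, 15, 15)
  expect_lt(sum(wfar[c(2:4, 6:8)]), 1e-6 * sum(wfar[c(1, 5)]))
})

test_that("open probability equals the brute-force 8-state enumeration", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_params()
    V <- stats::runif(1, -150, 250)
    pH_o <- stats::runif(1, 4, 9)
    pH_i <- stats::runif(1, 4, 9)
    expect_equal(open_probability(p, V, pH_o, pH_i),
                 oracle_popen(p, V, pH_o, pH_i), tolerance = 1e-12)
  }
})

test_that("open probability saturates at the voltage extremes and is monotone", {
  p <- amhv1_gating_params()
  expect_equal(open_probability(p, 5000, 7, 7), 1, tolerance = 1e-8)
  expect_lt(open_probability(p, -5000, 7, 7), 1e-8)
  expect_equal(open_probability(p, 0, 7, 7), 0.03861992, tolerance = 1e-6)
  V <- seq(-200, 300, by = 1)
  expect_true(all(diff(open_probability(p, V, 7, 6)) > 0))
})

test_that("detailed balance holds around every 4-cycle of the state graph", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_params()
    w <- state_weights(p, stats::runif(1, -100, 100),
                       stats::runif(1, 4, 9), stats::runif(1, 4, 9))
    # cycles: each face of the cube C/O x Bo x Bi; products of equilibrium
    # ratios around a loop must be 1 because weights are state functions
    cycles <- list(c("C", "CHo", "CHoHi", "CHi"),
                   c("O", "OHo", "OHoHi", "OHi"),
                   c("C", "O", "OHo", "CHo"),
                   c("C", "O", "OHi", "CHi"),
                   c("CHo", "OHo", "OHoHi", "CHoHi"),
                   c("CHi", "OHi", "OHoHi", "CHoHi"))
    for (cy in cycles) {
      r <- w[cy] / w[c(cy[-1], cy[1])]
      expect_equal(prod(r), 1, tolerance = 1e-9)
    }
  }
})

test_that("closed-form V0.5 agrees with a numeric root of the oracle", {
  p <- amhv1_gating_params()
  # frozen value for the ApH = 1 condition of the zinc experiments
  vh <- solve_v_half(p, 7, 6)
  expect_equal(vh, 81.5805, tolerance = 1e-4)
  root <- uniroot(function(v) oracle_popen(p, v, 7, 6) - 0.5,
                  c(vh - 5, vh + 5), tol = 1e-10)$root
  expect_equal(vh, root, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:25) {
    pr <- random_params()
    pH_o <- stats::runif(1, 4, 9); pH_i <- stats::runif(1, 4, 9)
    v <- solve_v_half(pr, pH_o, pH_i)
    expect_equal(open_probability(pr, v, pH_o, pH_i), 0.5, tolerance = 1e-9)
  }
})

test_that("V0.5 limits and shifts follow the closed form", {
  p <- amhv1_gating_params()
  VT <- thermal_voltage(295.15)
  # both proton sites empty: V0.5 -> VT/q_g * ln(1/Kv0)
  expect_equal(solve_v_half(p, 20, 20), VT * log(1 / 5e-5), tolerance = 1e-3)
  # doubling Kv0 shifts V0.5 by -VT ln(2)/q_g at any pH
  p2 <- allosteric_params(Kv0 = 1e-4, q_g = 1, C = 2e-4, D = 1e5, E = 5e5,
                          pK_o = 3.4, pK_i = 7)
  for (ph in list(c(7, 7), c(7, 5), c(6, 8)))
    expect_equal(solve_v_half(p2, ph[1], ph[2]) - solve_v_half(p, ph[1], ph[2]),
                 -VT * log(2), tolerance = 1e-9)
})

test_that("threshold voltage is monotone in fraction and matches V0.5 at 1/2", {
  p <- amhv1_gating_params()
  expect_equal(solve_v_threshold(p, 7, 6, 0.5), solve_v_half(p, 7, 6))
  v10 <- solve_v_threshold(p, 7, 6, 0.1)
  v30 <- solve_v_threshold(p, 7, 6, 0.3)
  expect_lt(v10, v30)
  expect_lt(v30, solve_v_half(p, 7, 6))
  expect_equal(open_probability(p, v10, 7, 6), 0.1, tolerance = 1e-8)
  expect_error(solve_v_threshold(p, 7, 6, 1), "fraction")
  expect_error(solve_v_threshold(p, 7, 6, 0), "fraction")
})

test_that("V0.5 vs delta-pH sweep is sigmoidal with two plateaus", {
  p <- amhv1_gating_params()
  pH_i <- seq(-2, 16, by = 0.1)
  sw <- v_half_vs_delta_ph(p, rep(7, length(pH_i)), pH_i)
  ord <- order(sw$delta_pH)
  expect_true(all(diff(sw$V_half_mV[ord]) <= 1e-9))  # decreasing in delta_pH
  # closed-form asymptotes of the two plateaus (sites saturated / empty)
  VT <- thermal_voltage(295.15)
  xo <- binding_weight(3.4, 7)
  lo <- VT * log((1 + p$E * xo) / (p$Kv0 * p$D * (1 + p$C * p$E * xo)))
  hi <- VT * log((1 + xo) / (p$Kv0 * (1 + p$C * xo)))
  expect_lt(abs(min(sw$V_half_mV) - lo), 1)   # within 1 mV of the asymptote
  expect_lt(abs(max(sw$V_half_mV) - hi), 1)
  # total swing matches its closed form
  swing <- VT * log(p$D * (1 + p$C * p$E * xo) * (1 + xo) /
                      ((1 + p$E * xo) * (1 + p$C * xo)))
  expect_equal(hi - lo, swing, tolerance = 1e-9)
  # steeper than the canonical -40 mV per pH unit somewhere on the curve
  slope <- diff(sw$V_half_mV[ord]) / diff(sw$delta_pH[ord])
  expect_gt(max(abs(slope)), 40)
})

test_that("neutral couplings make V0.5 independent of pH", {
  pn <- allosteric_params(Kv0 = 5e-5, q_g = 1, C = 1, D = 1, E = 1,
                          pK_o = 3.4, pK_i = 7)
  v <- v_half_vs_delta_ph(pn, rep(7, 8), seq(3, 10))$V_half_mV
  expect_equal(diff(range(v)), 0, tolerance = 1e-9)
})

test_that("parameter validation rejects non-physical sets", {
  expect_error(allosteric_params(-1, 1, 1, 1, 1, 7, 7), "positive")
  expect_error(allosteric_params(1, 0, 1, 1, 1, 7, 7), "q_g")
  expect_error(allosteric_params(1, 1, 1, 1, 1, 7, 7, temperature_K = -5),
               "temperature")
  expect_error(allosteric_params(1, 1, Inf, 1, 1, 7, 7), "finite")
})
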