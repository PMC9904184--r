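test_that("ideal-gas conversions are correct, linear, and validated", {
  const <- incubation_constants()

  expect_equal(pressure_to_moles(0, const), 0)
  # 0.75 psi in the 0.150 L headspace at 312.15 K
  kpa <- 0.75 * const$psi_to_kpa
  expect_equal(pressure_to_moles(kpa, const), 2.988639e-4, tolerance = 1e-6)
  expect_equal(pressure_to_moles(2 * kpa, const),
               2 * pressure_to_moles(kpa, const))

  expect_equal(moles_to_ml(1, const), 22400)
  expect_equal(moles_to_ml(0, const), 0)
  expect_equal(moles_to_ml(2.988639e-4, const), 6.694552, tolerance = 1e-6)

  expect_error(pressure_to_moles(-1, const), "non-negative")
  expect_error(moles_to_ml(-1e-6, const), "non-negative")
  expect_error(incubation_constants(headspace_l = 0), "positive")
  expect_error(incubation_constants(temperature_k = -1), "positive")
})

test_that("cumulative gas reconstruction handles vents and rejects inconsistent traces", {
  const <- incubation_constants()
  tt <- seq(0, 2, by = 0.5)

  # constant zero pressure, no vents -> all-zero curve
  tr0 <- pressure_trace("b0", tt, psi = rep(0, 5), substrate_mass_g = 1,
                        dm_fraction = 1)
  expect_equal(cumulative_gas(tr0, const)$gas, rep(0, 5))

  # a single 0.75 psi vent adds exactly volume(0.75)/g DM to later points
  vol_075 <- moles_to_ml(pressure_to_moles(0.75 * const$psi_to_kpa, const),
                         const)
  tr_novent <- pressure_trace("b1", tt, psi = c(0, 0.2, 0.4, 0.5, 0.6),
                              substrate_mass_g = 2, dm_fraction = 0.5)
  tr_vent <- pressure_trace("b2", tt, psi = c(0, 0.2, 0.4, 0.5, 0.6),
                            vented_psi = c(0, 0, 0.75, 0, 0),
                            substrate_mass_g = 2, dm_fraction = 0.5)
  g1 <- cumulative_gas(tr_novent, const)$gas
  g2 <- cumulative_gas(tr_vent, const)$gas
  expect_equal(g2[1:2], g1[1:2])
  expect_equal(g2[3:5], g1[3:5] + vol_075 / 1, tolerance = 1e-12)

  # conversion chain is linear in the trace
  tr_k <- pressure_trace("b3", tt, psi = 3 * c(0, 0.2, 0.4, 0.5, 0.6),
                         substrate_mass_g = 2, dm_fraction = 0.5)
  expect_equal(cumulative_gas(tr_k, const)$gas, 3 * g1, tolerance = 1e-12)

  # a drop without a vent is an inconsistent trace
  tr_bad <- pressure_trace("b4", tt, psi = c(0, 0.4, 0.2, 0.5, 0.6),
                           substrate_mass_g = 1, dm_fraction = 1)
  expect_error(cumulative_gas(tr_bad, const), "inconsistent")

  # trace invariants enforced at construction
  expect_error(pressure_trace("x", c(0, 1, 1), c(0, 1, 1),
                              substrate_mass_g = 1), "strictly increasing")
  expect_error(pressure_trace("x", c(0.5, 1), c(0, 1),
                              substrate_mass_g = 1), "time 0")
  expect_error(pressure_trace("x", c(0, 1), c(0.1, 1),
                              substrate_mass_g = 1), "0 psi")
  expect_error(pressure_trace("x", c(0, 1), c(0, 1), substrate_mass_g = 0),
               "positive")
})

test_that("blank correction subtracts the mean blank volume before DM normalisation", {
  tt <- 0:4
  curve <- structure(data.frame(time_h = tt, gas = c(0, 10, 20, 30, 40)),
                     per_g_dm = TRUE, g_dm = 2,
                     class = c("gas_curve", "data.frame"))
  blank <- function(v) structure(data.frame(time_h = tt, gas = v),
                                 per_g_dm = FALSE, g_dm = NA,
                                 class = c("gas_curve", "data.frame"))

  # all-zero blanks -> identity
  expect_equal(blank_correct(curve, list(blank(rep(0, 5))))$gas, curve$gas)

  # curve equal to the blank mean (per g DM) -> all-zero output
  eq <- curve
  eq$gas <- c(0, 5, 10, 15, 20) / 2
  expect_equal(blank_correct(eq, list(blank(c(0, 5, 10, 15, 20))))$gas,
               rep(0, 5))

  # two blanks of 10 and 20 mL subtract 15 mL (7.5 mL/g DM here)
  out <- blank_correct(curve, list(blank(rep(10, 5)), blank(rep(20, 5))))
  expect_equal(out$gas, curve$gas - 15 / 2)

  # negative corrected values are kept and counted, not clamped
  low <- curve
  low$gas <- rep(1, 5)
  out2 <- blank_correct(low, list(blank(rep(10, 5))))
  expect_true(all(out2$gas < 0))
  expect_equal(attr(out2, "n_negative"), 5)

  expect_warning(blank_correct(curve, list()), "no blank")
})

test_that("monophasic model satisfies its identities", {
  # direct evaluation
  expect_equal(monophasic_gas(5, 150, 10, 1.5), 39.18058, tolerance = 1e-6)
  expect_equal(monophasic_gas(0, 150, 10, 1.5), 0)

  # half-time identity and asymptote over random parameters
  set.seed(42)
  for (i in 1:50) {
    A <- runif(1, 100, 200); B <- runif(1, 6, 13); C <- runif(1, 1.2, 2)
    expect_equal(monophasic_gas(B, A, B, C), A / 2, tolerance = 1e-12)
    expect_equal(monophasic_gas(1e9, A, B, C), A, tolerance = 1e-6)
    g <- monophasic_gas(grid_10min(), A, B, C)
    expect_true(all(diff(g) > 0))
  }
  expect_error(monophasic_gas(-1, 150, 10, 1.5), "non-negative")
  expect_error(monophasic_gas(1, -1, 10, 1.5), "positive")
})

test_that("t_RM follows B(C-1)^(1/C) with an undefined marker for C <= 1", {
  expect_equal(t_rm(8.3, 1.62), 6.179094, tolerance = 1e-6)
  expect_equal(t_rm(12.1, 1.44), 6.842000, tolerance = 1e-6)
  expect_equal(t_rm(10, 2), 10)          # C = 2 -> t_RM = B exactly
  expect_true(is.na(t_rm(10, 1)))
  expect_true(is.na(t_rm(10, 0.8)))
  expect_error(t_rm(0, 1.5), "positive")
  expect_error(t_rm(5, -1), "positive")

  # t_RM < B on the fitted range 1 < C < 2 (equality at C = 2);
  # increasing in B at fixed C
  set.seed(7)
  B <- runif(40, 5, 15); C <- runif(40, 1.01, 2)
  expect_true(all(t_rm(B, C) <= B))
  for (cc in c(1.3, 1.7, 2.4)) {
    expect_true(all(diff(t_rm(sort(B), cc)) > 0))
  }
})

test_that("dry matter disappearance formula and flags", {
  expect_equal(dm_disappearance(1, 0), 100)
  expect_equal(dm_disappearance(1, 1), 0)
  expect_equal(dm_disappearance(1.1 * 0.93, 0.306), 70.08798,
               tolerance = 1e-6)
  expect_warning(d <- dm_disappearance(1, 1.2), "outside")
  expect_equal(d, -20)
  expect_error(dm_disappearance(0, 0.5), "positive")
})

test_that("fit_monophasic recovers known parameters and matches an independent optimiser", {
  tt <- grid_10min()

  # noiseless self-consistency across the parameter range
  set.seed(11)
  for (i in 1:8) {
    th <- c(A = runif(1, 100, 200), B = runif(1, 6, 13), C = runif(1, 1.2, 2))
    f <- fit_monophasic(make_curve(th["A"], th["B"], th["C"]))
    expect_true(f$converged)
    expect_lt(max(abs(coef(f) / th - 1)), 1e-6)
  }

  # C = 2 data gives t_RM = B
  f2 <- fit_monophasic(make_curve(150, 9, 2))
  expect_equal(f2$t_rm, f2$B, tolerance = 1e-6)

  # agreement with a Nelder-Mead oracle on noisy data
  set.seed(5)
  g <- monophasic_gas(tt, 164.5, 9.7, 1.8) + rnorm(length(tt), 0, 2)
  d <- data.frame(time_h = tt, gas = g)
  f3 <- fit_monophasic(d)
  orc <- oracle_fit(tt[tt > 0], g[tt > 0])
  expect_equal(unname(coef(f3)), unname(orc), tolerance = 1e-3)
  expect_lte(f3$rss, sum((g[tt > 0] - monophasic_gas(tt[tt > 0], orc["A"],
                                                     orc["B"], orc["C"]))^2) *
               (1 + 1e-6))

  # degenerate and undersized inputs
  expect_error(fit_monophasic(data.frame(time_h = tt, gas = 0 * tt)),
               "degenerate")
  expect_error(fit_monophasic(data.frame(time_h = 0:4, gas = c(0, 1, 2, 3, 4))),
               "at least 6")
})

test_that("monophasic_fit methods are coherent", {
  f <- fit_monophasic(make_curve(164.5, 9.7, 1.8))
  expect_named(coef(f), c("A", "B", "C"))
  expect_equal(predict(f, c(9.7)), f$A / 2, tolerance = 1e-4)
  expect_equal(length(residuals(f)), f$n_points)
  expect_equal(deviance(f), f$rss)
  expect_output(print(f), "Monophasic gas production fit")
  expect_output(print(summary(f)), "residual sd")
})

test_that("fit_gas_study assembles per-bottle fits with blank correction and dDM", {
  sc <- gas_scenario(truth = default_gas_truth()[c(4, 10), ],
                     n_replicates = 2, rep_sdlog = 0, noise_sd_psi = 0,
                     n_blanks = 2, seed = 21)
  sim <- simulate_incubation(sc)
  res_g <- setNames(rep(0.3, nrow(sim$bottles)), sim$bottles$bottle_id)
  out <- fit_gas_study(sim$traces, sc$constants, blank_correction = TRUE,
                       residue_g = res_g)
  expect_equal(nrow(out), 4)         # blanks are excluded from the rows
  expect_true(all(out$converged))
  # blank subtraction removes the inoculum background exactly here
  expect_equal(out$A, sim$truth$A[!sim$truth$is_blank], tolerance = 1e-5)
  # without the correction the background inflates the asymptote
  out_raw <- fit_gas_study(sim$traces, sc$constants, blank_correction = FALSE)
  expect_true(all(out_raw$A > out$A))
  expect_equal(out$dDM,
               rep(dm_disappearance(1.1 * 0.93, 0.3), 4), tolerance = 1e-12)
})
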