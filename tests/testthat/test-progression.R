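# Breath-to-breath progression: gamma update, compensatory pressure
# scaling, recruitment-curve drift, variable frequency and the simulation
# orchestrator.

p <- resp_params()

test_that("gamma update interpolates between no loss and full loss", {
  expect_equal(gamma_update(1, 0.95, 1), 0.95)  # all unrecruited lost
  expect_equal(gamma_update(0.8, 0.7, 0), 0.8)  # none lost
  expect_equal(gamma_update(0.9, 0.81, 0.1), 0.891)
  expect_error(gamma_update(0.8, 0.9, 0.1), "inconsistency")
  expect_error(gamma_update(1, 0.9, 2), "\\[0, 1\\]")
})

test_that("compensatory expansion reproduces the three-alveoli example", {
  # three units double their volume (radius +25%); one closes and the
  # remaining two must supply the same volume change (radius +35%)
  ce <- compensatory_expansion(2, 1/3)
  expect_equal(ce$rho0, 0.25, tolerance = 0.015 / 0.25)
  expect_equal(ce$rho1, 0.35, tolerance = 0.015 / 0.35)
  expect_equal(ce$u_comp, 2.5)
  expect_error(compensatory_expansion(1, 0.1), "degenerate")
  expect_error(compensatory_expansion(2, 1), "F_closed")
})

test_that("pressure scale factor: limits, monotonicity, both readings", {
  expect_equal(pressure_scale_factor(2, 0), 1)
  expect_equal(pressure_scale_factor(2, 0, method = "increase_ratio"), 1)
  # closed-form oracle: u = 2, half closed -> u' = 3
  expect_equal(pressure_scale_factor(2, 0.5, method = "increase_ratio"),
               (3^(1/3) - 1) / (2^(1/3) - 1))
  expect_equal(pressure_scale_factor(2, 0.5), (3/2)^(1/3))
  for (m in c("radius_ratio", "increase_ratio")) {
    s <- vapply(seq(0, 0.9, by = 0.1), pressure_scale_factor, 1,
                u = 2, method = m)
    expect_true(all(diff(s) > 0))
    expect_true(all(s >= 1))
  }
})

test_that("recruitment drift shifts the curve right and only right", {
  rec <- recruitment_state()
  full <- list(EILV = 30, EELV = 25, Frec_EI = rec$gamma)
  expect_equal(update_recruitment(rec, full, p)$cF, rec$cF)  # no closure
  part <- list(EILV = 30, EELV = 25, Frec_EI = 0.99)
  r2 <- update_recruitment(rec, part, p)
  expect_gt(r2$cF, rec$cF)
  expect_gt(r2$dF, rec$dF)
  expect_equal(r2$gamma, rec$gamma)  # p = 0 leaves the ceiling
  # the drifted curve lies at or below the old one for all P >= 0
  Pg <- seq(0, 40, by = 0.1)
  expect_true(all(recruited_fraction(Pg, r2) <=
                  recruited_fraction(Pg, rec) + 1e-12))
  # baseline constraint survives the drift
  expect_equal(recruited_fraction(0, r2), r2$beta, tolerance = 1e-12)
  expect_error(update_recruitment(rec, list(EILV = 24, EELV = 22,
                                            Frec_EI = 0.9), p),
               "degenerate")
})

test_that("variable frequency follows the minute-ventilation demand", {
  expect_equal(next_frequency(6, 360, "variable"), 1)
  expect_equal(next_frequency(3, 360, "variable"), 2)
  expect_equal(next_frequency(rep(c(5, 7), 5), 360, "variable"), 1)
  # moving window: only the last 60 values count
  h <- c(rep(100, 50), rep(6, 60))
  expect_equal(next_frequency(h, 360, "variable"), 1)
  expect_equal(next_frequency(6, 360, "constant", f_init = 1.5), 1.5)
  expect_equal(next_frequency(0.001, 360, "variable", f_cap = 3), 3)
})

test_that("high chest-wall compliance drives progressive collapse to failure", {
  sim <- sim_cached("S3")
  expect_false(is.na(sim$TTF))
  b <- sim$breaths
  # tidal volume ends below 10% of its starting value
  expect_lte(b$VT[nrow(b)], 0.1 * b$VT[1])
  # EELV decays monotonically through the descending-compliance regime
  tail_idx <- seq(floor(nrow(b) * 0.6), nrow(b))
  expect_true(all(diff(b$EELV[tail_idx]) < 1e-6))
  # recruitment parameters only ever drift rightward
  expect_true(all(diff(b$cF) > -1e-15))
  expect_true(all(diff(b$dF) > -1e-15))
})

test_that("simulations are deterministic", {
  s1 <- suppressWarnings(run_simulation(load_scenario("S3", max_breaths = 120)))
  s2 <- suppressWarnings(run_simulation(load_scenario("S3", max_breaths = 120)))
  expect_identical(s1$breaths, s2$breaths)
})

test_that("CPAP activates at its trigger and extends breathing", {
  sim <- sim_cached("S11")
  s3 <- sim_cached("S3")
  cb <- sim$interventions$cpap_breath
  expect_false(is.na(cb))
  b <- sim$breaths
  expect_lt(b$Frec_EI[cb], 0.90)
  expect_true(all(b$Frec_EI[seq_len(cb - 1)] >= 0.90))
  expect_true(all(b$Pao[seq_len(cb)] == 0))
  expect_true(all(b$Pao[(cb + 1):nrow(b)] == 5))
  expect_gt(sim$TTF, s3$TTF)
})

test_that("variable frequency holds minute ventilation near target", {
  sim <- cached("S3var",
                run_simulation(load_scenario("S3",
                                             frequency_mode = "variable")))
  b <- sim$breaths
  mid <- b[b$index > 60 & b$index < sim$failure_breath - 50, ]
  expect_lt(max(abs(mid$VE - 360)), 15)
  expect_gt(max(mid$f), min(mid$f))  # the rate actually moved
})

test_that("an apneic event inserts silent breaths at the scheduled time", {
  sim <- cached("S3ae",
                run_simulation(load_scenario("S3",
                                             frequency_mode = "variable",
                                             apnea = TRUE)))
  aw <- sim$interventions$apnea_window
  expect_false(is.null(aw))
  b <- sim$breaths
  idx <- seq(aw["start_breath"], length.out = aw["n_breaths"])
  expect_true(all(b$apneic[idx]))
  expect_true(all(b$Amus[idx] == 0))
  # the first silent breath still carries the relaxation transient from
  # the preceding driven breath; the rest are nearly flat
  expect_true(all(b$VT[idx[-1]] < 0.5))
  # apnea begins once the simulated clock passes its start time
  expect_gte(b$t_start[aw["start_breath"]], 120)
  expect_lt(b$t_start[aw["start_breath"]], 125)
  # breathing resumes afterwards
  after <- b$index > max(idx) & b$index < max(idx) + 20
  expect_gt(max(b$VT[after]), 2)
})
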