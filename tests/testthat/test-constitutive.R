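# Resistance and compliance constitutive laws: printed examples, limiting
# behaviour, inverse round trips and the analytic compliance derivative.

p <- resp_params()
rec <- recruitment_state()

test_that("upper airway Rohrer resistance combines laminar and turbulent parts", {
  expect_equal(upper_airway_resistance(0, p), 20)
  expect_equal(upper_airway_resistance(0.05, p, expiratory_multiplier = 10),
               23)   # inspiration: multiplier inactive
  expect_equal(upper_airway_resistance(-0.05, p, expiratory_multiplier = 10),
               230)  # expiration: 10 * (20 + 60 * 0.05)
  expect_error(upper_airway_resistance(NaN, p), "finite")
  expect_error(upper_airway_resistance(0.1, p, expiratory_multiplier = 0.5),
               ">= 1")
  flows <- seq(-1, 1, by = 0.01)
  expect_true(all(upper_airway_resistance(flows, p) >= p$Rum))
})

test_that("collapsible airway resistance follows the inverse-square law", {
  expect_equal(collapsible_resistance(2.5, p), 0.1)   # fully open: Kc
  expect_equal(collapsible_resistance(1.25, p), 0.4)
  expect_equal(collapsible_resistance(0.25, p), 10)
  expect_error(collapsible_resistance(0, p), "degenerate")
  v <- seq(0.1, 2.5, by = 0.1)
  expect_true(all(diff(collapsible_resistance(v, p)) < 0))
})

test_that("small airway resistance decays from Rsd+Rsm at RV to ~Rsm at TLC", {
  expect_equal(small_airway_resistance(23, p), 32)
  expect_equal(small_airway_resistance(63, p), 20 * exp(-15) + 12)
  expect_equal(small_airway_resistance(43, p), 20 * exp(-7.5) + 12,
               tolerance = 1e-10)
  v <- seq(23, 63, by = 1)
  expect_true(all(small_airway_resistance(v, p) >= p$Rsm))
})

test_that("collapsible-airway PV sigmoid inverts exactly", {
  expect_equal(collapsible_volume(4.4, p), 1.25)  # midpoint = Vcmax/2
  expect_equal(collapsible_volume(1e4, p), 2.5)   # upper asymptote
  for (Ptm in c(-10, 0, 4.4, 20))
    expect_equal(collapsible_pressure(collapsible_volume(Ptm, p), p), Ptm,
                 tolerance = 1e-10)
  expect_error(collapsible_pressure(2.5, p), "clamp")
  expect_error(collapsible_pressure(0, p), "clamp")
})

test_that("chest-wall softplus passes through V0 and inverts exactly", {
  p35 <- resp_params(V0 = 35)
  expect_equal(chest_wall_volume(0, p35), 35)      # relaxation volume
  expect_equal(chest_wall_volume(0, p), p$V0)
  expect_equal(chest_wall_volume(-40, p), p$RV, tolerance = 1e-10)
  for (V in c(23.5, 30, 40))
    expect_equal(chest_wall_pressure(chest_wall_volume(
      chest_wall_pressure(V, p), p), p), chest_wall_pressure(V, p),
      tolerance = 1e-10)
  expect_error(chest_wall_pressure(23, p), "exceed RV")
  # above RV everywhere, approaching it at large negative recoil;
  # strictly monotone where the softplus is numerically resolvable
  Pg <- seq(-30, 60, by = 0.5)
  Vg <- chest_wall_volume(Pg, p)
  expect_true(all(Vg >= p$RV))
  expect_true(all(diff(Vg) >= 0))
  expect_true(all(diff(chest_wall_volume(seq(-8, 60, by = 0.5), p)) > 0))
  expect_lt(chest_wall_volume(-40, p) - p$RV, 1e-10)
  slope_hi <- (chest_wall_volume(100.1, p) - chest_wall_volume(99.9, p)) / 0.2
  expect_equal(slope_hi, p$bw / p$dw, tolerance = 1e-4)
})

test_that("alpha satisfies the baseline recruitment constraint", {
  expect_equal(alpha_from_constraint(0.01, 1, 0.1, 0.4), -0.76,
               tolerance = 0.005)
  # degenerate flat case: beta = gamma forces alpha = gamma
  expect_equal(alpha_from_constraint(0.7, 0.7, 0.1, 0.4), 0.7)
  # property: F_rec(0) recovers beta for arbitrary parameters
  set.seed(42)
  for (i in 1:25) {
    beta <- runif(1, 1e-3, 0.3); gamma <- runif(1, beta + 0.05, 1)
    cF <- runif(1, 0.05, 3); dF <- runif(1, 0.1, 2)
    r <- recruitment_state(beta, gamma, cF, dF)
    expect_equal(recruited_fraction(0, r), beta, tolerance = 1e-12)
  }
})

test_that("recruited fraction is a sigmoid from beta to gamma", {
  expect_equal(recruited_fraction(0, rec), 0.01)
  expect_equal(recruited_fraction(1e4, rec), 1)
  expect_equal(recruited_fraction(rec$cF, rec), (rec$alpha + rec$gamma) / 2)
  Pg <- seq(-5, 40, by = 0.1)
  expect_true(all(diff(recruited_fraction(Pg, rec)) >= 0))
  expect_true(all(diff(recruited_fraction(seq(-5, 10, by = 0.1), rec)) > 0))
})

test_that("lung volume runs from RV to TLC", {
  expect_equal(lung_volume(0, p, rec), 23)
  expect_equal(lung_volume(1e4, p, rec), 63)
  # recoil at the high-Cw resting point maps near the published FRC
  expect_gt(lung_volume(0.954, p, rec), 24.9)
  expect_lt(lung_volume(0.954, p, rec), 25.2)
  Pg <- seq(0, 40, by = 0.1)
  expect_true(all(diff(lung_volume(Pg, p, rec)) > 0))
})

test_that("analytic alveolar compliance matches the finite difference", {
  h <- 1e-4
  for (Pel in c(0.5, 1, 2, 5, 10)) {
    fd <- (lung_volume(Pel + h, p, rec) - lung_volume(Pel - h, p, rec)) /
      (2 * h)
    expect_equal(alveolar_compliance(Pel, p, rec), fd,
                 tolerance = 1e-6)
  }
  # at zero recoil only the distension term survives: VC * k * beta
  expect_equal(alveolar_compliance(0, p, rec), 40 * 0.07 * 0.01)
  Pg <- seq(0, 40, by = 0.1)
  expect_true(all(alveolar_compliance(Pg, p, rec) > 0))
})

test_that("parameter constructor enforces its invariants", {
  expect_equal(p$VC, p$TLC - p$RV)
  expect_equal(p$bw, (p$V0 - p$RV) / log(2))
  expect_equal(resp_params(V0 = 35)$bw, 17.3, tolerance = 0.02)
  expect_equal(p$aw, p$RV)
  expect_equal(p$bc, p$Vcmax)
  expect_error(resp_params(TLC = 20, RV = 23), "TLC > RV")
  expect_error(resp_params(Ks = 1), "negative")
  expect_error(resp_params(Kc = -1), "non-positive")
  expect_error(recruitment_state(beta = 0.5, gamma = 0.4), "beta < gamma")
})
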