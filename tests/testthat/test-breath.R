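# Single-breath engine: muscle driver, pressure algebra, RHS fixed point,
# integration, conservation, steady state and the braking effect.

p <- resp_params()
rec <- recruitment_state()

test_that("muscle pressure is a rectified cosine with range [-2A, 0]", {
  expect_equal(muscle_pressure(0, 1.85, 1), 0)
  expect_equal(muscle_pressure(0.5, 1.85, 1), -3.7)
  expect_equal(muscle_pressure(0.25, 2, 1), -2)
  expect_equal(muscle_pressure(1, 1.85, 1), 0, tolerance = 1e-12)
  tt <- seq(0, 1, by = 0.01)
  expect_true(all(muscle_pressure(tt, 2, 1) <= 1e-12))
  expect_true(all(muscle_pressure(tt, 2, 1) >= -4))
})

test_that("the RHS vanishes at the constant-drive equilibrium", {
  st <- find_equilibrium(p, rec)
  ctl <- list(params = p, rec = rec, A_mus = 0, f = 1)
  d <- resp_rhs(0, st, ctl)[[1]]
  expect_lt(sqrt(sum(d^2)), 1e-8)
  # resting pressure algebra: transmural equals recoil when flow is zero
  der <- compute_derived(0, matrix(st, 1), ctl)
  expect_lt(abs(der$Ptm - der$Pel), 1e-6)
  expect_lt(abs(der$flowA), 1e-9)
})

test_that("a CPAP pressure step accelerates inspiratory flow", {
  st <- find_equilibrium(p, rec)
  ctl <- list(params = p, rec = rec, A_mus = 0, f = 1, Pao = 5)
  d <- resp_rhs(0, st, ctl)[[1]]
  expect_gt(d[1], 0)
})

test_that("compiled and reference R right-hand sides integrate identically", {
  eq <- compute_frc(p, rec)
  st0 <- initial_conditions(eq)
  bc <- integrate_breath(st0, p, rec, A_mus = 1.85, f = 1,
                         use_compiled = TRUE)
  br <- integrate_breath(st0, p, rec, A_mus = 1.85, f = 1,
                         use_compiled = FALSE)
  for (col in c("flow", "Vc", "Pel", "Pve"))
    expect_equal(bc$trace[[col]], br$trace[[col]], tolerance = 1e-5)
  expect_equal(bc$summary$VT, br$summary$VT, tolerance = 1e-4)
})

test_that("without a driver there is no tidal volume", {
  eq <- compute_frc(p, rec)
  st <- find_equilibrium(p, rec)   # start settled so no transient VT
  b <- integrate_breath(st, p, rec, A_mus = 0, f = 1)
  expect_lt(b$summary$VT, 1e-6)
})

test_that("breathing converges to a periodic steady state within 10 breaths", {
  s <- steady_condition("high_normal")
  expect_lte(s$n_breaths, 12)
  b2 <- integrate_breath(s$end_state, p, rec, A_mus = 1.85, f = 1)
  expect_equal(b2$summary$VT, s$summary$VT, tolerance = 1e-3)
})

test_that("volume conservation and closed-loop flow hold on the steady breath", {
  s <- steady_condition("high_normal")
  tr <- s$trace
  expect_equal(tr$Vcw, tr$VA + tr$Vc)   # identity by construction
  # net alveolar flow over a closed cycle ~ 0 (trapezoid, ml)
  net <- 1000 * sum(diff(tr$t) * (head(tr$flowA, -1) + tail(tr$flowA, -1)) / 2)
  expect_lt(abs(net), 0.005 * s$summary$VT)
  # derived pressure identities
  expect_equal(tr$PA, tr$Pel + tr$Pve + tr$Ppl)
  expect_equal(tr$Pl_dyn, tr$PA - tr$Ppl, tolerance = 1e-12)
})

test_that("laryngeal braking raises peak alveolar pressure several-fold", {
  pa_norm <- max(steady_condition("high_normal")$trace$PA)
  pa_brk <- max(steady_condition("high_braked")$trace$PA)
  expect_gt(pa_brk / pa_norm, 3)
  expect_lt(pa_brk / pa_norm, 6)
})

test_that("a stiffer chest wall raises EELV and deepens pleural pressure", {
  hi <- steady_condition("high_normal")
  lo <- steady_condition("low_normal")
  expect_gt(lo$summary$EELV, hi$summary$EELV)
  expect_lt(min(lo$trace$Ppl), min(hi$trace$Ppl))
})

test_that("breath summaries satisfy their defining identities", {
  for (nm in names(condition_grid)) {
    s <- steady_condition(nm)$summary
    expect_equal(s$VT, s$EILV - s$EELV)
    expect_gte(s$VT, 0)
    expect_equal(s$VE, 60 * s$f * s$VT)
    expect_gte(s$PIP, s$Pel_EI)
  }
})
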