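# Static parameterization: functional residual capacity from the combined
# relaxation curve, initial conditions, dynamic-compliance metrics, and
# calibration of the muscle pressure amplitude to a target minute
# ventilation.

#' Functional residual capacity of the relaxed respiratory system
#'
#' FRC is the volume at which lung elastic recoil and chest-wall recoil
#' balance, `P_el(V) + P_cw(V) = 0`.  The crossing is found as a scalar
#' root in recoil pressure of `P + P_cw(V_A(P))` over the physiological
#' pressure range and refined to a residual below `tol`.
#'
#' @param params a [resp_params()] object.
#' @param rec a [recruitment_state()] object (the published parameterization
#'   uses the baseline curve with `gamma = 1`).
#' @param pressure_range search interval for the recoil pressure, cm H2O.
#' @param tol tolerance on the pressure residual `|P_el + P_cw|`, cm H2O.
#' @return An object of class `resp_equilibrium`: list with `FRC` (ml),
#'   `Pel_at_FRC`, `Pcw_at_FRC` (= -`Pel_at_FRC`), `residual` and `tol`.
#' @examples
#' compute_frc(resp_params())            # high chest-wall compliance
#' compute_frc(resp_params(dw = 2.4))    # low chest-wall compliance
#' @export
compute_frc <- function(params, rec = recruitment_state(),
                        pressure_range = c(1e-6, 40), tol = 1e-6) {
  g <- function(P) P + chest_wall_pressure(
    pmax(lung_volume(P, params, rec), params$RV + 1e-9), params)
  lo <- pressure_range[1]; hi <- pressure_range[2]
  if (g(lo) * g(hi) > 0)
    stop("parameterization error: no recoil balance in the pressure range")
  r <- stats::uniroot(g, c(lo, hi), tol = tol * 1e-3)
  res <- list(FRC = lung_volume(r$root, params, rec),
              Pel_at_FRC = r$root, Pcw_at_FRC = -r$root,
              residual = g(r$root), tol = tol)
  class(res) <- "resp_equilibrium"
  res
}

#' @export
print.resp_equilibrium <- function(x, ...) {
  cat(sprintf("FRC %.4g ml at Pel %.4g cm H2O (residual %.2g)\n",
              x$FRC, x$Pel_at_FRC, x$residual))
  invisible(x)
}

#' Initial conditions for breath-by-breath simulation
#'
#' The simulation starts from rest: no airflow, the collapsible airway
#' nearly empty (0.0001 ml), lung recoil at its FRC value and no
#' viscoelastic stress.  The near-empty collapsible segment produces a
#' stiff first-breath transient, which is why reported steady-state metrics
#' use a burn-in (see [steady_state_breath()]).
#'
#' @param eq a `resp_equilibrium` from [compute_frc()].
#' @return Named numeric state vector `(flow, Vc, Pel, Pve)`.
#' @export
initial_conditions <- function(eq) {
  c(flow = 0, Vc = 1e-4, Pel = eq$Pel_at_FRC, Pve = 0)
}

#' Dynamic compliances of one breath
#'
#' Secant-slope compliances between the end-inspiratory and end-expiratory
#' instants of a breath trace: lung `CL = dVA/dPel`, chest wall
#' `Cw = dVcw/dPcw`, and the series (harmonic) respiratory-system value
#' `Crs = (1/CL + 1/Cw)^-1`.
#'
#' @param trace a breath trace data frame from [integrate_breath()] (needs
#'   columns `VA`, `Vcw`, `Pel`, `Pcw`).
#' @return List with `CL`, `Cw`, `Crs`, all ml/cm H2O.
#' @export
dynamic_compliances <- function(trace) {
  iEI <- which.max(trace$VA); iEE <- which.min(trace$VA)
  dPel <- trace$Pel[iEI] - trace$Pel[iEE]
  dPcw <- trace$Pcw[iEI] - trace$Pcw[iEE]
  if (abs(dPel) < 1e-12 || abs(dPcw) < 1e-12)
    stop("degenerate breath: no pressure excursion")
  CL <- (trace$VA[iEI] - trace$VA[iEE]) / dPel
  Cw <- (trace$Vcw[iEI] - trace$Vcw[iEE]) / dPcw
  list(CL = CL, Cw = Cw, Crs = 1 / (1 / CL + 1 / Cw))
}

#' Periodic steady-state breath
#'
#' Integrates successive breaths with the recruitment curve frozen until
#' tidal volume converges (relative change below `vt_tol` after at least
#' `burn_in` breaths), then returns the converged breath.  Used for the
#' steady-state output tables and for calibration.
#'
#' @inheritParams integrate_breath
#' @param burn_in minimum number of breaths before convergence is tested.
#' @param max_breaths giving-up point.
#' @param vt_tol relative tidal-volume change defining convergence.
#' @return As [integrate_breath()], plus `n_breaths` used.
#' @export
steady_state_breath <- function(params, rec, A_mus, f = 1, Pao = 0,
                                brake = 1, burn_in = 10, max_breaths = 40,
                                vt_tol = 1e-3, n_points = 101) {
  eq <- compute_frc(params, rec)
  state <- initial_conditions(eq)
  VT_prev <- NA_real_
  for (b in seq_len(max_breaths)) {
    out <- .breath_core(state, params, rec, A_mus, f, Pao, brake, n_points)
    state <- unname(out[nrow(out), 2:5])
    VA <- lung_volume(out[, 4], params, rec)
    VT <- max(VA) - min(VA)
    if (b > burn_in && is.finite(VT_prev) &&
        abs(VT - VT_prev) < vt_tol * VT_prev) break
    VT_prev <- VT
  }
  ctl <- list(params = params, rec = rec, A_mus = A_mus, f = f,
              Pao = Pao, brake = brake)
  list(trace = compute_derived(out[, 1], out[, 2:5], ctl),
       summary = .breath_summary(out, params, rec, A_mus, f, Pao, brake,
                                 index = b),
       end_state = state, n_breaths = b)
}

#' Calibrate the muscle pressure amplitude to a target minute ventilation
#'
#' Finds `A_mus` such that the steady-state minute ventilation
#' `VE = 60 f VT` equals `target_VE`, by scalar root finding on the model's
#' own steady-state simulation (no analytic shortcut: the tidal volume
#' depends on all the nonlinearities).
#'
#' @inheritParams steady_state_breath
#' @param target_VE target minute ventilation, ml/min.
#' @param interval bracketing interval for `A_mus`, cm H2O.
#' @param tol acceptable deviation of VE from target, ml/min.
#' @return Calibrated amplitude, cm H2O.
#' @examples
#' \donttest{
#' calibrate_amus(resp_params(), recruitment_state())  # ~1.9 cm H2O
#' }
#' @export
calibrate_amus <- function(params, rec, target_VE = 360, f = 1, Pao = 0,
                           brake = 1, interval = c(0.1, 20), tol = 0.5) {
  ve <- function(A) {
    s <- steady_state_breath(params, rec, A_mus = A, f = f, Pao = Pao,
                             brake = brake, n_points = 51)
    s$summary$VE - target_VE
  }
  flo <- ve(interval[1]); fhi <- ve(interval[2])
  if (flo * fhi > 0)
    stop("calibration error: target VE not bracketed on the interval")
  r <- stats::uniroot(function(A) ve(A), interval,
                      f.lower = flo, f.upper = fhi, tol = 1e-4)
  if (abs(r$f.root) > tol)
    warning("calibration residual ", signif(r$f.root, 3), " ml/min")
  r$root
}
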