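# The ODE core: right-hand side assembly from the constitutive laws and the
# Kirchhoff pressure loops, one-breath integration with a stiff solver, and
# per-breath summaries.

#' Sinusoidal respiratory muscle driving pressure
#'
#' `Pmus(t) = Amus cos(2 pi f t) - Amus`: zero at end-expiration (t = 0 and
#' t = 1/f), maximally negative (-2 Amus) at mid-breath.
#'
#' @param t time within the breath, s.
#' @param A_mus amplitude, cm H2O.
#' @param f breathing frequency, breaths/s.
#' @return Muscle pressure, cm H2O (<= 0).
#' @export
muscle_pressure <- function(t, A_mus, f) {
  A_mus * cos(2 * pi * f * t) - A_mus
}

# parameter vector consumed by the compiled RHS; order must match src/resp_rhs.c
.parvec <- function(params, rec, A_mus, f, Pao = 0, brake = 1) {
  c(params$TLC, params$RV, params$VC, params$k,
    rec$alpha, rec$gamma, rec$cF, rec$dF,
    params$cw, params$dw, params$bw,
    params$cc, params$dc, params$Kc, params$Vcmax,
    params$Rsm, params$Rsd, params$Ks,
    params$Iu, params$Rum, params$Ku, brake,
    params$Cve, params$Rve, Pao, A_mus, f)
}

.clamp_vc <- function(Vc, params) {
  pmin(pmax(Vc, 1e-6), params$Vcmax - 1e-6)
}

#' Model right-hand side (reference R implementation)
#'
#' Derivatives of the four states (airflow, collapsible-airway volume, lung
#' recoil pressure, viscoelastic pressure) assembled from the constitutive
#' laws via the mesh pressure loops.  This R version is the readable
#' reference; [integrate_breath()] normally calls the identical compiled
#' version shipped in the package's C code.  Exposed for stability analysis
#' and cross-checking.
#'
#' @param t time within the breath, s.
#' @param state numeric state vector `(flow, Vc, Pel, Pve)`.
#' @param controls a list with members `params` ([resp_params()]), `rec`
#'   ([recruitment_state()]), `A_mus`, `f`, and optionally `Pao` (airway
#'   opening pressure, default 0) and `brake` (expiratory Ru multiplier,
#'   default 1).
#' @return A list whose first element is the derivative vector (deSolve
#'   convention).
#' @export
resp_rhs <- function(t, state, controls) {
  p <- controls$params; rec <- controls$rec
  Pao <- if (is.null(controls$Pao)) 0 else controls$Pao
  brake <- if (is.null(controls$brake)) 1 else controls$brake
  flow <- state[[1]]; Vc <- state[[2]]; Pel <- state[[3]]; Pve <- state[[4]]

  VA   <- lung_volume(Pel, p, rec)
  Vcw  <- VA + Vc
  Pcw  <- chest_wall_pressure(max(Vcw, p$RV + 1e-9), p)
  Ppl  <- Pcw + muscle_pressure(t, controls$A_mus, controls$f)
  Vcc  <- .clamp_vc(Vc, p)
  Ptm  <- collapsible_pressure(Vcc, p)
  flowA <- (Ptm - Pel - Pve) / small_airway_resistance(VA, p)   # L/s
  Pu   <- Ptm + Ppl + collapsible_resistance(Vcc, p) * flow
  Ru   <- upper_airway_resistance(flow, p, brake)

  list(c(dflow = (Pao - Pu - Ru * flow) / p$Iu,
         dVc   = 1000 * (flow - flowA),
         dPel  = 1000 * flowA / alveolar_compliance(Pel, p, rec),
         dPve  = (flowA - Pve / p$Rve) / p$Cve))
}

#' Derived pressures, volumes and flows along a state trace
#'
#' Completes a state trace with every algebraic quantity of the model:
#' chest-wall, pleural, transmural, alveolar and dynamic pulmonary
#' pressures, compartment volumes and the alveolar airflow.  Satisfies the
#' conservation law `Vcw = VA + Vc` by construction.
#'
#' @param times numeric vector of within-breath times, s.
#' @param states numeric matrix (or vector for a single instant) with
#'   columns `flow, Vc, Pel, Pve`.
#' @inheritParams resp_rhs
#' @return A data frame with columns `t, flow, Vc, Pel, Pve, VA, Vcw, Pcw,
#'   Pmus, Ppl, Ptm, Pc, Pu, PA, Pl_dyn, Pao, flowA, Ru, Rc, Rs`.
#' @export
compute_derived <- function(times, states, controls) {
  p <- controls$params; rec <- controls$rec
  Pao <- if (is.null(controls$Pao)) 0 else controls$Pao
  brake <- if (is.null(controls$brake)) 1 else controls$brake
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  flow <- states[, 1]; Vc <- states[, 2]; Pel <- states[, 3]; Pve <- states[, 4]

  VA   <- lung_volume(Pel, p, rec)
  Vcw  <- VA + Vc
  Pcw  <- chest_wall_pressure(pmax(Vcw, p$RV + 1e-9), p)
  Pmus <- muscle_pressure(times, controls$A_mus, controls$f)
  Ppl  <- Pcw + Pmus
  Vcc  <- .clamp_vc(Vc, p)
  Ptm  <- collapsible_pressure(Vcc, p)
  Pc   <- Ptm + Ppl
  Rs   <- small_airway_resistance(VA, p)
  flowA <- (Ptm - Pel - Pve) / Rs
  Rc   <- collapsible_resistance(Vcc, p)
  Pu   <- Pc + Rc * flow
  Ru   <- upper_airway_resistance(flow, p, brake)
  PA   <- Pel + Pve + Ppl

  data.frame(t = times, flow = flow, Vc = Vc, Pel = Pel, Pve = Pve,
             VA = VA, Vcw = Vcw, Pcw = Pcw, Pmus = Pmus, Ppl = Ppl,
             Ptm = Ptm, Pc = Pc, Pu = Pu, PA = PA, Pl_dyn = Pel + Pve,
             Pao = Pao, flowA = flowA, Ru = Ru, Rc = Rc, Rs = Rs)
}

# fast internal one-breath integration; returns the raw deSolve matrix
.breath_core <- function(state0, params, rec, A_mus, f, Pao = 0, brake = 1,
                         n_points = 101, rtol = 1e-6, atol = 1e-8) {
  times <- seq(0, 1 / f, length.out = n_points)
  pv <- .parvec(params, rec, A_mus, f, Pao, brake)
  out <- deSolve::ode(y = unname(state0), times = times,
                      func = "resp_derivs", parms = pv,
                      dllname = "respsim", initfunc = "resp_init",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("breath integration failed (solver state ",
         attr(out, "istate")[1], ")")
  out
}

# per-breath summary as a plain numeric vector (hot path: run_simulation
# builds one of these per breath, so no data.frame allocation here)
.summary_fields <- c("index", "f", "VT", "EELV", "EILV", "PIP", "Frec_EI",
                     "Pel_EI", "Pel_EE", "CL", "Cw_dyn", "Crs", "VE",
                     "Rrs_min", "Rrs_max", "Pao", "Amus", "cF", "dF",
                     "gamma", "t_start", "apneic")

.breath_summary_vec <- function(out, params, rec, A_mus, f, Pao, brake,
                                index, t_start = 0, apneic = FALSE) {
  Pel <- out[, 4]
  VA  <- lung_volume(Pel, params, rec)
  iEI <- which.max(VA); iEE <- which.min(VA)
  Vc  <- out[, 3]
  Vcw <- VA + Vc
  Pcw <- chest_wall_pressure(pmax(Vcw, params$RV + 1e-9), params)
  VT  <- VA[iEI] - VA[iEE]
  dPel <- Pel[iEI] - Pel[iEE]
  dPcw <- Pcw[iEI] - Pcw[iEE]
  CL <- if (abs(dPel) > 1e-12) VT / dPel else NA_real_
  Cw <- if (abs(dPcw) > 1e-12) (Vcw[iEI] - Vcw[iEE]) / dPcw else NA_real_
  Rrs <- upper_airway_resistance(out[, 2], params, brake) +
    collapsible_resistance(.clamp_vc(Vc, params), params) +
    small_airway_resistance(VA, params)
  c(index, f, VT, VA[iEE], VA[iEI], max(Pel),
    recruited_fraction(Pel[iEI], rec), Pel[iEI], Pel[iEE],
    CL, Cw,
    if (is.na(CL) || is.na(Cw)) NA_real_ else 1 / (1 / CL + 1 / Cw),
    60 * f * VT, min(Rrs), max(Rrs), Pao, A_mus,
    rec$cF, rec$dF, rec$gamma, t_start, as.numeric(apneic))
}

# per-breath summary from a raw solution matrix
.breath_summary <- function(out, params, rec, A_mus, f, Pao, brake,
                            index = 1L) {
  Pel <- out[, 4]
  VA  <- lung_volume(Pel, params, rec)
  iEI <- which.max(VA); iEE <- which.min(VA)
  Vc  <- out[, 3]
  Vcw <- VA + Vc
  Pcw <- chest_wall_pressure(pmax(Vcw, params$RV + 1e-9), params)
  VT  <- VA[iEI] - VA[iEE]
  dPel <- Pel[iEI] - Pel[iEE]
  dPcw <- Pcw[iEI] - Pcw[iEE]
  CL <- if (abs(dPel) > 0) VT / dPel else NA_real_
  Cw <- if (abs(dPcw) > 0) (Vcw[iEI] - Vcw[iEE]) / dPcw else NA_real_
  Rrs <- upper_airway_resistance(out[, 2], params, brake) +
    collapsible_resistance(.clamp_vc(Vc, params), params) +
    small_airway_resistance(VA, params)
  data.frame(index = index, f = f, VT = VT,
             EELV = VA[iEE], EILV = VA[iEI], PIP = max(Pel),
             Frec_EI = recruited_fraction(Pel[iEI], rec),
             Pel_EI = Pel[iEI], Pel_EE = Pel[iEE],
             CL = CL, Cw_dyn = Cw,
             Crs = if (is.na(CL) || is.na(Cw)) NA_real_
                   else 1 / (1 / CL + 1 / Cw),
             VE = 60 * f * VT,
             Rrs_min = min(Rrs), Rrs_max = max(Rrs),
             Pao = Pao, Amus = A_mus,
             cF = rec$cF, dF = rec$dF, gamma = rec$gamma)
}

#' Integrate a single breath
#'
#' Solves the four-state system over one breathing cycle `[0, 1/f]` with a
#' stiff solver (lsoda; relative tolerance 1e-6, absolute 1e-8), starting
#' from the end state of the previous breath.  End-inspiration (EI) and
#' end-expiration (EE) are located at the maximum and minimum of alveolar
#' volume along the trace, from which tidal volume, dynamic compliances and
#' the recruited fraction at EI are derived.
#'
#' @param state0 numeric state vector `(flow, Vc, Pel, Pve)`, typically from
#'   [initial_conditions()] or a previous breath's `end_state`.
#' @param params a [resp_params()] object.
#' @param rec a [recruitment_state()] object.
#' @param A_mus muscle pressure amplitude, cm H2O.
#' @param f breathing frequency, breaths/s (> 0).
#' @param Pao airway-opening (CPAP) pressure, cm H2O.
#' @param brake expiratory upper-airway resistance multiplier (>= 1).
#' @param n_points number of equally spaced output instants per breath.
#' @param rtol,atol solver tolerances.
#' @param use_compiled integrate with the package's compiled RHS (default)
#'   or the reference R implementation [resp_rhs()].
#' @return A list with `trace` (data frame of states plus all derived
#'   quantities, from [compute_derived()]), `summary` (one-row data frame:
#'   `VT`, `EELV`, `EILV`, `PIP`, `Frec_EI`, dynamic compliances, `VE`,
#'   respiratory-system resistance range), and `end_state`.
#' @examples
#' \donttest{
#' p <- resp_params(); r <- recruitment_state()
#' eq <- compute_frc(p, r)
#' b <- integrate_breath(initial_conditions(eq), p, r, A_mus = 1.85, f = 1)
#' b$summary$VT
#' }
#' @export
integrate_breath <- function(state0, params, rec, A_mus, f, Pao = 0,
                             brake = 1, n_points = 101,
                             rtol = 1e-6, atol = 1e-8,
                             use_compiled = TRUE) {
  stopifnot(f > 0)
  if (use_compiled) {
    out <- .breath_core(state0, params, rec, A_mus, f, Pao, brake,
                        n_points, rtol, atol)
  } else {
    times <- seq(0, 1 / f, length.out = n_points)
    ctl <- list(params = params, rec = rec, A_mus = A_mus, f = f,
                Pao = Pao, brake = brake)
    out <- deSolve::ode(y = unname(state0), times = times, func = resp_rhs,
                        parms = ctl, method = "lsoda",
                        rtol = rtol, atol = atol)
  }
  ctl <- list(params = params, rec = rec, A_mus = A_mus, f = f,
              Pao = Pao, brake = brake)
  trace <- compute_derived(out[, 1], out[, 2:5], ctl)
  end_state <- unname(out[nrow(out), 2:5])
  list(trace = trace,
       summary = .breath_summary(out, params, rec, A_mus, f, Pao, brake),
       end_state = end_state)
}
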