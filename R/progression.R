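# Breath-to-breath progression: recruitment-curve drift driven by the
# compensatory over-distension of open alveoli, the permanent-closure
# gamma update, variable breathing frequency, interventions and the
# whole-simulation orchestrator with failure detection.

#' Update the maximum recruitable fraction after a breath
#'
#' A fraction `p` of the alveoli that failed to recruit at end-inspiration
#' is assumed permanently lost:
#' `gamma_next = gamma (1 - p F_closed)` with
#' `F_closed = 1 - F_rec_EI / gamma`, so that `p = 1` makes the observed
#' end-inspiratory recruited fraction the new ceiling and `p = 0` leaves
#' `gamma` untouched.
#'
#' @param gamma current maximum recruitable fraction, in (0, 1].
#' @param Frec_EI recruited fraction at end-inspiration of the completed
#'   breath; must not exceed `gamma`.
#' @param p permanently-closing fraction per breath, in `[0, 1]`.
#' @return The updated gamma, in `[Frec_EI, gamma]`.
#' @export
gamma_update <- function(gamma, Frec_EI, p) {
  if (Frec_EI > gamma + 1e-12)
    stop("state inconsistency: Frec_EI exceeds gamma")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  Fclosed <- 1 - min(Frec_EI, gamma) / gamma
  gamma * (1 - p * Fclosed)
}

#' Compensatory expansion of open alveoli when a fraction closes
#'
#' If alveoli expand their volume by a factor `u` over a breath, their
#' radius grows by `rho0 = u^(1/3) - 1`.  When a fraction `F_closed` of
#' units is closed, the remaining open units must produce the same
#' aggregate volume change, i.e. a per-unit volume ratio
#' `u' = 1 + (u - 1)/(1 - F_closed)`, requiring the larger radius increase
#' `rho1 = u'^(1/3) - 1`.  (With a third of doubling units closed:
#' `rho0` = 26%, `rho1` = 36% — the familiar "25% becomes 35%" example.)
#'
#' @param u per-breath tidal expansion ratio of the aerated lung (> 1).
#' @param F_closed closed fraction, in `[0, 1)`.
#' @return List with `u_comp` (compensated volume ratio), `rho0` and `rho1`
#'   (fractional radius increases without and with closure).
#' @export
compensatory_expansion <- function(u, F_closed) {
  if (u <= 1) stop("degenerate breath: no tidal expansion (u <= 1)")
  if (F_closed < 0 || F_closed >= 1) stop("F_closed must be in [0, 1)")
  u_comp <- 1 + (u - 1) / (1 - F_closed)
  list(u_comp = u_comp, rho0 = u^(1/3) - 1, rho1 = u_comp^(1/3) - 1)
}

#' Pressure scale factor shifting the recruitment curve
#'
#' The distending pressure needed for the compensatory over-expansion of
#' open units scales the recruitment-curve pressure parameters `cF` and
#' `dF` each breath.  Two readings of "the pressure increases in proportion
#' to the radius change" are provided:
#' \describe{
#'   \item{`"radius_ratio"` (default)}{`s = (u'/u)^(1/3)`, the ratio of the
#'     final radii with and without closure.}
#'   \item{`"increase_ratio"`}{`s = rho1/rho0`, the ratio of the fractional
#'     radius increases.}
#' }
#' Both give `s = 1` with no closure and grow with `F_closed`; the default
#' reproduces the published high-chest-wall-compliance failure-time scale.
#'
#' @inheritParams compensatory_expansion
#' @param method which proportionality reading to use.
#' @return Scale factor `s >= 1`.
#' @examples
#' pressure_scale_factor(2, 0)        # 1: no closure, no shift
#' pressure_scale_factor(2, 1/3, method = "increase_ratio")  # ~1.37
#' @export
pressure_scale_factor <- function(u, F_closed,
                                  method = c("radius_ratio",
                                             "increase_ratio")) {
  method <- match.arg(method)
  ce <- compensatory_expansion(u, F_closed)
  if (method == "radius_ratio") (ce$u_comp / u)^(1/3)
  else ce$rho1 / ce$rho0
}

#' Drift the recruitment curve after a completed breath
#'
#' Implements the progressive volume-loss mechanism: the tidal expansion
#' ratio of the aerated lung `u = (EILV - RV)/(EELV - RV)` and the closed
#' fraction at end-inspiration `F_closed = 1 - F_rec_EI/gamma` determine a
#' pressure scale factor `s` ([pressure_scale_factor()]); `cF` and `dF` are
#' multiplied by `s` (rightward shift of the compliance curve), `gamma`
#' decays by the permanent-closure rule ([gamma_update()]) and `alpha` is
#' recomputed so the baseline constraint still holds.  The update is
#' applied between breaths; the curve is constant within a breath.
#'
#' @param rec current [recruitment_state()].
#' @param breath one-row breath summary (from [integrate_breath()]):
#'   needs `EILV`, `EELV`, `Frec_EI`.
#' @param params a [resp_params()] object.
#' @param p permanently-closing fraction per breath.
#' @param method drift proportionality reading, see
#'   [pressure_scale_factor()].
#' @return The drifted `recruitment_state`.
#' @export
update_recruitment <- function(rec, breath, params, p = 0,
                               method = c("radius_ratio",
                                          "increase_ratio")) {
  method <- match.arg(method)
  if (breath$EELV <= params$RV)
    stop("degenerate state: EELV at or below residual volume")
  u <- (breath$EILV - params$RV) / (breath$EELV - params$RV)
  Fclosed <- 1 - min(breath$Frec_EI, rec$gamma) / rec$gamma
  s <- if (u > 1 + 1e-9) pressure_scale_factor(u, Fclosed, method) else 1
  g <- gamma_update(rec$gamma, min(breath$Frec_EI, rec$gamma), p)
  r <- list(beta = rec$beta, gamma = g, cF = s * rec$cF, dF = s * rec$dF,
            alpha = alpha_from_constraint(rec$beta, g, s * rec$cF,
                                          s * rec$dF))
  class(r) <- "recruitment_state"
  r
}

#' Breathing frequency from the minute-ventilation demand
#'
#' In variable-frequency mode the respiratory rate follows
#' `VE = VT_ave * f`: `f = target_VE/(60 VT_ave)` breaths/s, where `VT_ave`
#' is a moving average of up to the last 60 tidal volumes (about one minute
#' of breathing).  The frequency is capped to keep it physiological as
#' tidal volume collapses near failure.
#'
#' @param VT_history numeric vector of completed tidal volumes, ml (most
#'   recent last); at least one element.
#' @param target_VE target minute ventilation, ml/min.
#' @param mode `"constant"` returns `f_init` unchanged.
#' @param f_init initial frequency, breaths/s.
#' @param f_cap maximum frequency, breaths/s.
#' @return Frequency, breaths/s.
#' @export
next_frequency <- function(VT_history, target_VE = 360,
                           mode = c("constant", "variable"),
                           f_init = 1, f_cap = 3) {
  mode <- match.arg(mode)
  if (mode == "constant") return(f_init)
  if (length(VT_history) == 0) return(f_init)
  VT_ave <- mean(utils::tail(VT_history, 60))
  if (VT_ave <= 0.01) return(f_cap)
  min(target_VE / (60 * VT_ave), f_cap)
}

#' Run a breath-by-breath simulation to failure
#'
#' Chains [integrate_breath()] and [update_recruitment()] until tidal
#' breathing fails — tidal volume fallen to
#' `(1 - failure_fraction)` of its initial value — or `max_breaths` is
#' reached.  Interventions follow the scenario configuration: CPAP steps
#' the airway-opening pressure up permanently at the first breath whose
#' end-inspiratory recruited fraction drops below the trigger; laryngeal
#' braking multiplies the expiratory upper-airway resistance throughout;
#' a single apneic event suspends the muscle drive for its configured
#' duration; variable-frequency mode retunes the respiratory rate each
#' breath from the minute-ventilation demand.
#'
#' @param scenario a [scenario_config()] (or a registry name passed to
#'   [load_scenario()]).
#' @param keep_traces keep the full state trace of every `keep_traces`-th
#'   breath (0 = none) in the result.
#' @param quiet suppress per-100-breath progress messages.
#' @return An object of class `resp_sim`: list with `breaths` (one summary
#'   row per breath), `TTF` (time to failure, hours, `NA` if censored),
#'   `failure_breath`, `interventions` (CPAP activation breath, apnea
#'   window), `scenario`, `final_rec`, and optionally `traces`.
#' @examples
#' \donttest{
#' sim <- run_simulation(load_scenario("S3"))
#' sim$TTF   # ~0.3 h under high chest-wall compliance, no intervention
#' }
#' @export
run_simulation <- function(scenario, keep_traces = 0, quiet = TRUE) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  sc <- scenario
  params <- sc$params
  rec <- sc$rec
  eq <- compute_frc(params, recruitment_state(beta = rec$beta, cF = rec$cF,
                                              dF = rec$dF))
  state <- initial_conditions(eq)
  f <- sc$f_init
  brake <- if (sc$braking) sc$brake_multiplier else 1
  Pao <- 0

  n_alloc <- min(sc$max_breaths, 4096L)
  rows <- matrix(NA_real_, n_alloc, length(.summary_fields))
  traces <- list()
  VT_hist <- numeric(sc$max_breaths)
  VT_ref <- NA_real_
  t_cum <- 0
  cpap_breath <- NA_integer_
  apnea_window <- NULL
  apnea_left <- 0L
  failure_breath <- NA_integer_
  TTF <- NA_real_
  b <- 0L

  for (b in seq_len(sc$max_breaths)) {
    apneic <- apnea_left > 0L
    A_b <- if (apneic) 0 else sc$A_mus
    out <- .breath_core(state, params, rec, A_b, f, Pao, brake,
                        n_points = sc$n_points,
                        rtol = sc$rtol, atol = sc$atol)
    state <- unname(out[nrow(out), 2:5])
    summ <- .breath_summary_vec(out, params, rec, A_b, f, Pao, brake,
                                index = b, t_start = t_cum, apneic = apneic)
    t_cum <- t_cum + 1 / f
    if (b > nrow(rows))
      rows <- rbind(rows, matrix(NA_real_, nrow(rows),
                                 length(.summary_fields)))
    rows[b, ] <- summ
    VT <- summ[[3]]; EELV <- summ[[4]]; EILV <- summ[[5]]
    Frec_EI <- summ[[7]]
    if (keep_traces > 0 && (b %% keep_traces == 1 || keep_traces == 1)) {
      ctl <- list(params = params, rec = rec, A_mus = A_b, f = f,
                  Pao = Pao, brake = brake)
      traces[[as.character(b)]] <- compute_derived(out[, 1], out[, 2:5], ctl)
    }
    if (!quiet && b %% 100 == 0)
      message(sprintf("breath %d: VT %.3f ml, f %.2f, gamma %.4f, cF %.3f",
                      b, VT, f, rec$gamma, rec$cF))

    if (b == 1) VT_ref <- VT
    if (!apneic && b > 1 && VT <= (1 - sc$failure_fraction) * VT_ref) {
      failure_breath <- b
      TTF <- t_cum / 3600
      break
    }

    # recruitment drift between breaths (skip the flat apneic "breaths")
    if (!apneic && EILV > EELV && EELV > params$RV)
      rec <- update_recruitment(
        rec,
        list(EILV = EILV, EELV = EELV, Frec_EI = Frec_EI),
        params, p = sc$permanent_fraction, method = sc$drift_scaling)

    # CPAP: one-time permanent step of the airway-opening pressure
    if (!is.na(sc$cpap_trigger) && is.na(cpap_breath) &&
        Frec_EI < sc$cpap_trigger) {
      Pao <- sc$cpap_pressure
      cpap_breath <- b
    }

    # frequency for the next breath
    VT_hist[b] <- VT
    f <- next_frequency(VT_hist[max(1L, b - 59L):b], sc$target_VE,
                        sc$frequency_mode, sc$f_init, sc$f_cap)

    # schedule a single apneic event once simulated time passes its start
    if (apneic) {
      apnea_left <- apnea_left - 1L
    } else if (sc$apnea && is.null(apnea_window) &&
               t_cum >= sc$apnea_start) {
      apnea_left <- as.integer(ceiling(sc$apnea_duration * f))
      apnea_window <- c(start_breath = b + 1L,
                        n_breaths = apnea_left)
    }
  }
  if (is.na(failure_breath))
    warning("max_breaths reached without failure; TTF censored")

  breaths <- as.data.frame(rows[seq_len(b), , drop = FALSE])
  names(breaths) <- .summary_fields
  breaths$apneic <- as.logical(breaths$apneic)
  res <- list(breaths = breaths, TTF = TTF,
              failure_breath = failure_breath,
              censored_at = if (is.na(failure_breath)) t_cum / 3600
                            else NA_real_,
              interventions = list(cpap_breath = cpap_breath,
                                   apnea_window = apnea_window),
              scenario = sc, final_rec = rec,
              traces = if (keep_traces > 0) traces else NULL)
  class(res) <- "resp_sim"
  res
}

#' @export
print.resp_sim <- function(x, ...) {
  cat(sprintf("Breath-by-breath simulation: %s\n", x$scenario$name))
  cat(sprintf("  %d breaths simulated\n", nrow(x$breaths)))
  if (!is.na(x$TTF))
    cat(sprintf("  failure at breath %d; TTF = %.3f h\n",
                x$failure_breath, x$TTF))
  else
    cat(sprintf("  no failure (censored at %.3f h)\n", x$censored_at))
  if (!is.na(x$interventions$cpap_breath))
    cat(sprintf("  CPAP %g cm H2O from breath %d\n",
                x$scenario$cpap_pressure, x$interventions$cpap_breath))
  invisible(x)
}

#' Plot breath-by-breath volumes of a simulation
#'
#' End-expiratory lung volume (left axis) and tidal volume (right axis)
#' against breath number, the standard view of progressive volume loss.
#'
#' @param x a `resp_sim` from [run_simulation()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.resp_sim <- function(x, ...) {
  b <- x$breaths
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(b$index, b$EELV, type = "l", col = "steelblue",
                 xlab = "breath", ylab = "EELV [ml]",
                 main = x$scenario$name, ...)
  graphics::par(new = TRUE)
  graphics::plot(b$index, b$VT, type = "l", col = "firebrick",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("VT [ml]", side = 4, line = 2.5)
  invisible(x)
}
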