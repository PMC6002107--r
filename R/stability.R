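# Local stability analysis under constant (non-oscillatory) muscle
# pressure: equilibrium solving, finite-difference Jacobian, eigenvalues
# and a parameter-multiple sweep.

#' Equilibrium state under constant muscle pressure
#'
#' With a constant drive the four-state system has a rest point with zero
#' airflow and relaxed viscoelastic stress, at which the remaining
#' conditions reduce exactly to one scalar equation in recoil pressure:
#' `Pel + Pcw(VA(Pel) + Vc(Pel)) + Pmus - Pao = 0` with
#' `Vc = collapsible_volume(Pel)` (transmural pressure equals recoil when
#' alveolar flow vanishes).  The root is found by bisection and the full
#' right-hand side residual verified below `tol`.
#'
#' @param params a [resp_params()] object.
#' @param rec a [recruitment_state()] object.
#' @param Pmus constant muscle pressure, cm H2O (<= 0).
#' @param Pao airway-opening pressure, cm H2O.
#' @param tol residual tolerance on the RHS norm.
#' @return Named state vector `(flow, Vc, Pel, Pve)` with attribute
#'   `residual`.
#' @examples
#' find_equilibrium(resp_params(), recruitment_state())
#' @export
find_equilibrium <- function(params, rec, Pmus = 0, Pao = 0, tol = 1e-8) {
  if (Pmus > 0) stop("constant muscle pressure must be <= 0")
  g <- function(Pel) {
    Vc <- collapsible_volume(Pel, params)
    Vcw <- lung_volume(Pel, params, rec) + Vc
    Pel + chest_wall_pressure(pmax(Vcw, params$RV + 1e-9), params) +
      Pmus - Pao
  }
  r <- stats::uniroot(g, c(1e-6, 60), tol = 1e-12, extendInt = "upX")
  Pel <- r$root
  state <- c(flow = 0, Vc = collapsible_volume(Pel, params),
             Pel = Pel, Pve = 0)
  deriv <- .rhs_const(state, params, rec, Pmus, Pao)
  res <- sqrt(sum(deriv^2))
  if (res > tol)
    stop("equilibrium residual ", signif(res, 3), " exceeds tolerance")
  attr(state, "residual") <- res
  state
}

# RHS under a constant muscle pressure (no time dependence)
.rhs_const <- function(state, params, rec, Pmus, Pao = 0, brake = 1) {
  p <- params
  flow <- state[[1]]; Vc <- state[[2]]; Pel <- state[[3]]; Pve <- state[[4]]
  VA  <- lung_volume(Pel, p, rec)
  Vcw <- VA + Vc
  Pcw <- chest_wall_pressure(max(Vcw, p$RV + 1e-9), p)
  Ppl <- Pcw + Pmus
  Vcc <- .clamp_vc(Vc, p)
  Ptm <- collapsible_pressure(Vcc, p)
  flowA <- (Ptm - Pel - Pve) / small_airway_resistance(VA, p)
  Pu  <- Ptm + Ppl + collapsible_resistance(Vcc, p) * flow
  Ru  <- upper_airway_resistance(flow, p, brake)
  c((Pao - Pu - Ru * flow) / p$Iu,
    1000 * (flow - flowA),
    1000 * flowA / alveolar_compliance(Pel, p, rec),
    (flowA - Pve / p$Rve) / p$Cve)
}

#' Finite-difference Jacobian of the model RHS
#'
#' Central differences with per-state steps `max(step, step * |state|)`:
#' the states span four orders of magnitude (airflow ~0.02 L/s vs volumes
#' ~1-30 ml), so a pure absolute step would be ill-scaled.
#'
#' @inheritParams find_equilibrium
#' @param state state vector at which to differentiate.
#' @param step base finite-difference step.
#' @return 4 x 4 Jacobian matrix.
#' @export
rhs_jacobian <- function(state, params, rec, Pmus = 0, Pao = 0,
                         step = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(step, step * abs(state[[j]]))
    sp <- sm <- state
    sp[[j]] <- sp[[j]] + h
    sm[[j]] <- sm[[j]] - h
    J[, j] <- (.rhs_const(sp, params, rec, Pmus, Pao) -
               .rhs_const(sm, params, rec, Pmus, Pao)) / (2 * h)
  }
  J
}

#' Stability report at an equilibrium
#'
#' Eigenvalues of the finite-difference Jacobian at the constant-drive
#' equilibrium; the model is locally stable when all real parts are
#' negative.
#'
#' @inheritParams find_equilibrium
#' @return An object of class `stability_report`: list with `equilibrium`,
#'   `eigenvalues` (complex, decreasing real part), `stable`, `residual`.
#' @examples
#' stability_report(resp_params(), recruitment_state())$stable  # TRUE
#' @export
stability_report <- function(params, rec, Pmus = 0, Pao = 0) {
  st <- find_equilibrium(params, rec, Pmus, Pao)
  ev <- eigen(rhs_jacobian(st, params, rec, Pmus, Pao),
              only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  rep <- list(equilibrium = st, eigenvalues = ev,
              stable = all(Re(ev) < 0),
              residual = attr(st, "residual"))
  class(rep) <- "stability_report"
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Equilibrium: Pel %.4g, Vc %.4g (residual %.2g)\n",
              x$equilibrium[["Pel"]], x$equilibrium[["Vc"]], x$residual))
  cat("Eigenvalues (1/s):\n")
  for (e in x$eigenvalues)
    cat(sprintf("  %10.4g %+.4gi\n", Re(e), Im(e)))
  cat(if (x$stable) "stable (all real parts negative)\n"
      else "UNSTABLE\n")
  invisible(x)
}

#' Stability sweep over parameter multiples
#'
#' Recomputes the constant-drive equilibrium and Jacobian eigenvalues with
#' each tunable parameter scaled by the given multiples (2 and 10 by
#' default), flagging any destabilised case.  Per-case failures are
#' recorded and the sweep continues.
#'
#' @inheritParams find_equilibrium
#' @param multiples numeric multipliers applied one parameter at a time.
#' @param parameters names of [resp_params()] members to scale.
#' @return Data frame with columns `parameter`, `multiple`,
#'   `max_re_eigenvalue`, `stable`, `error`.
#' @export
stability_sweep <- function(params, rec, multiples = c(2, 10),
                            parameters = c("k", "dw", "cc", "dc", "Kc",
                                           "Rsm", "Rsd", "Iu", "Rum", "Ku",
                                           "Cve", "Rve"),
                            Pmus = 0, Pao = 0) {
  grid <- expand.grid(parameter = parameters, multiple = multiples,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pm <- grid$parameter[i]; mu <- grid$multiple[i]
    out <- data.frame(parameter = pm, multiple = mu,
                      max_re_eigenvalue = NA_real_, stable = NA,
                      error = NA_character_)
    tryCatch({
      p2 <- params
      p2[[pm]] <- p2[[pm]] * mu
      rep <- stability_report(p2, rec, Pmus, Pao)
      out$max_re_eigenvalue <- max(Re(rep$eigenvalues))
      out$stable <- rep$stable
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  do.call(rbind, rows)
}
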