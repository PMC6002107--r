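#' Fixed mechanical parameters of the respiratory system
#'
#' Bundles every constant of the lumped-parameter model: lung volumes,
#' airway resistance coefficients, compliance-curve shape constants and the
#' viscoelastic tissue element.  Defaults are the tuned values for a ~1 kg
#' extremely preterm infant; only the chest-wall slope `dw` (and, for the
#' laryngeal-braking condition, the upper-airway constants) vary between
#' simulated conditions.
#'
#' The chest-wall softplus curve is anchored by its relaxation volume
#' `V0` (volume at `Pcw = 0`); its slope constant is derived as
#' `bw = (V0 - RV)/log(2)` so that the curve passes through `V0` exactly.
#' By default `V0 = nu*VC + RV`.  The lower asymptote `aw` equals `RV` and
#' the collapsible-airway upper asymptote `bc` equals `Vcmax`; both aliases
#' are stored for completeness.
#'
#' @param TLC total lung capacity, ml.
#' @param RV residual volume, ml.
#' @param nu chest-wall relaxation volume as a fraction of vital capacity.
#' @param V0 chest-wall relaxation volume, ml; default `nu*(TLC - RV) + RV`.
#' @param dw chest-wall compliance slope constant, cm H2O. 0.48 gives the
#'   high-compliance (floppy) chest wall, 2.4 the low-compliance (stiff) one.
#' @param cw chest-wall transition point, cm H2O.
#' @param k aggregate lung elasticity, 1/cm H2O.
#' @param cc,dc collapsible-airway sigmoid centre and slope, cm H2O.
#' @param Kc collapsible-airway resistance coefficient, cm H2O.s/L.
#' @param Vcmax maximal collapsible-airway volume (dead-space estimate), ml.
#' @param Rsm,Rsd minimum and decaying components of small-airway
#'   resistance, cm H2O.s/L.
#' @param Ks small-airway resistance exponent (dimensionless, negative).
#' @param Iu upper-airway inertance, cm H2O.s^2/L.
#' @param Rum,Ku laminar and turbulent Rohrer coefficients of upper-airway
#'   resistance, cm H2O.s/L.
#' @param Cve viscoelastic compliance, L/cm H2O.
#' @param Rve viscoelastic resistance, cm H2O.s/L.
#' @return An object of class `resp_params`: a validated list with the
#'   derived members `VC`, `bw`, and the aliases `aw`, `ac`, `bc`.
#' @examples
#' p <- resp_params()           # high chest-wall compliance defaults
#' p_low <- resp_params(dw = 2.4)
#' p$bw                          # derived from V0
#' @export
resp_params <- function(TLC = 63, RV = 23, nu = 0.25, V0 = NULL,
                        dw = 0.48, cw = 0, k = 0.07,
                        cc = 4.4, dc = 4.4, Kc = 0.1, Vcmax = 2.5,
                        Rsm = 12, Rsd = 20, Ks = -15,
                        Iu = 0.33, Rum = 20, Ku = 60,
                        Cve = 0.005, Rve = 20) {
  if (!(is.finite(TLC) && is.finite(RV) && TLC > RV && RV > 0))
    stop("need TLC > RV > 0")
  VC <- TLC - RV
  if (is.null(V0)) V0 <- nu * VC + RV
  if (V0 <= RV) stop("V0 must exceed RV")
  bw <- (V0 - RV) / log(2)
  pos <- c(dw = dw, k = k, dc = dc, Kc = Kc, Vcmax = Vcmax, Rsm = Rsm,
           Rsd = Rsd, Iu = Iu, Rum = Rum, Ku = Ku, Cve = Cve, Rve = Rve)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("non-positive parameter: ",
         paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "))
  if (Ks >= 0) stop("Ks must be negative")
  p <- list(TLC = TLC, RV = RV, VC = VC, nu = nu, V0 = V0,
            aw = RV, bw = bw, cw = cw, dw = dw, k = k,
            ac = 0, bc = Vcmax, cc = cc, dc = dc, Kc = Kc, Vcmax = Vcmax,
            Rsm = Rsm, Rsd = Rsd, Ks = Ks, Iu = Iu, Rum = Rum, Ku = Ku,
            Cve = Cve, Rve = Rve)
  class(p) <- "resp_params"
  p
}

#' @export
print.resp_params <- function(x, ...) {
  cat("Respiratory mechanical parameters\n")
  cat(sprintf("  volumes [ml]: TLC %.4g  RV %.4g  VC %.4g  V0 %.4g (bw %.4g)\n",
              x$TLC, x$RV, x$VC, x$V0, x$bw))
  cat(sprintf("  chest wall: dw %.3g cm H2O   lung: k %.3g /cm H2O\n",
              x$dw, x$k))
  cat(sprintf("  airways: Ru = %.3g + %.3g|V'|  Rs in [%.3g, %.3g]  Kc %.3g  Iu %.3g\n",
              x$Rum, x$Ku, x$Rsm, x$Rsm + x$Rsd, x$Kc, x$Iu))
  cat(sprintf("  viscoelastic: Cve %.3g L/cm H2O  Rve %.3g\n", x$Cve, x$Rve))
  invisible(x)
}

#' Lower asymptote of the recruitment sigmoid from the baseline constraint
#'
#' Solves `F_rec(0) = beta` for the lower asymptote `alpha` of the
#' recruited-fraction sigmoid
#' `F_rec(P) = alpha + (gamma - alpha) / (1 + exp(-(P - cF)/dF))`,
#' giving `alpha = ((1 + E) beta - gamma)/E` with `E = exp(cF/dF)`.
#'
#' @param beta recruited fraction at zero recoil pressure, in (0, 1).
#' @param gamma maximum recruitable fraction, in (0, 1].
#' @param cF mean opening pressure, cm H2O (> 0).
#' @param dF recruitment heterogeneity (sigmoid slope), cm H2O (> 0).
#' @return The lower asymptote (dimensionless, typically negative).
#' @examples
#' alpha_from_constraint(0.01, 1, 0.1, 0.4)  # -0.761
#' @export
alpha_from_constraint <- function(beta, gamma, cF, dF) {
  if (dF <= 0) stop("dF must be positive")
  E <- exp(cF / dF)
  ((1 + E) * beta - gamma) / E
}

#' Mutable state of the alveolar recruitment curve
#'
#' The recruited fraction of alveoli is a sigmoid in lung elastic recoil
#' pressure with mean opening pressure `cF`, heterogeneity `dF`, ceiling
#' `gamma` and baseline `beta` at zero recoil.  The lower asymptote `alpha`
#' is always derived from the other four via [alpha_from_constraint()] so
#' that `F_rec(0) = beta` holds exactly; it drifts breath-to-breath as the
#' curve parameters change (see [update_recruitment()]).
#'
#' @param beta baseline recruited fraction at `Pel = 0`, in (0, 1).
#' @param gamma maximum recruitable fraction, in `(beta, 1]`.
#' @param cF mean opening pressure, cm H2O (> 0).
#' @param dF heterogeneity / sigmoid slope, cm H2O (> 0).
#' @return An object of class `recruitment_state` with derived `alpha`.
#' @examples
#' r <- recruitment_state()
#' recruited_fraction(0, r)   # equals beta
#' @export
recruitment_state <- function(beta = 0.01, gamma = 1, cF = 0.1, dF = 0.4) {
  if (!(beta > 0 && beta < gamma && gamma <= 1))
    stop("need 0 < beta < gamma <= 1")
  if (cF <= 0 || dF <= 0) stop("cF and dF must be positive")
  r <- list(beta = beta, gamma = gamma, cF = cF, dF = dF,
            alpha = alpha_from_constraint(beta, gamma, cF, dF))
  class(r) <- "recruitment_state"
  r
}

#' @export
print.recruitment_state <- function(x, ...) {
  cat(sprintf(
    "Recruitment curve: beta %.3g  gamma %.4g  cF %.4g  dF %.4g  (alpha %.4g)\n",
    x$beta, x$gamma, x$cF, x$dF, x$alpha))
  invisible(x)
}
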