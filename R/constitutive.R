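# Constitutive relations: every resistance and compliance law of the model,
# the invertible pressure-volume curves, and the analytic alveolar
# compliance dV_A/dP_el.  All functions are pure and vectorised over their
# pressure/volume/flow argument.

# numerically stable softplus and its inverse
.softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
.inv_softplus <- function(y) {
  # solves log(1 + e^x) = y for x; for large y, e^y - 1 ~ e^y
  ifelse(y > 30, y, log(expm1(y)))
}

#' Upper-airway (Rohrer) resistance
#'
#' Flow-dependent resistance `Ru = m (Rum + Ku |flow|)` combining laminar
#' and turbulent components.  The multiplier `m` models laryngeal braking
#' (grunting): it is applied only during expiration (`flow < 0`), raising
#' both components, and equals 1 otherwise.
#'
#' @param flow airflow, L/s (positive inspiratory).
#' @param params a [resp_params()] object.
#' @param expiratory_multiplier braking multiplier, >= 1 (10 reproduces the
#'   published laryngeal-braking condition).
#' @return Resistance, cm H2O.s/L; never below `Rum`.
#' @examples
#' p <- resp_params()
#' upper_airway_resistance(0.05, p)                            # 23
#' upper_airway_resistance(-0.05, p, expiratory_multiplier = 10)  # 230
#' @export
upper_airway_resistance <- function(flow, params, expiratory_multiplier = 1) {
  if (any(!is.finite(flow))) stop("flow must be finite")
  if (expiratory_multiplier < 1) stop("expiratory_multiplier must be >= 1")
  m <- ifelse(flow < 0, expiratory_multiplier, 1)
  m * (params$Rum + params$Ku * abs(flow))
}

#' Collapsible-airway resistance
#'
#' Poiseuille-type resistance of the collapsible middle airway,
#' `Rc = Kc (Vcmax / Vc)^2`, minimal (`Kc`) when the segment is fully open.
#'
#' @param Vc collapsible-airway volume, ml (> 0).
#' @inheritParams upper_airway_resistance
#' @return Resistance, cm H2O.s/L.
#' @export
collapsible_resistance <- function(Vc, params) {
  if (any(Vc <= 0)) stop("degenerate state: Vc must be positive")
  params$Kc * (params$Vcmax / Vc)^2
}

#' Small (peripheral) airway resistance
#'
#' Decaying exponential in relative lung volume with a finite value at
#' `VA = 0`: `Rs = Rsd exp(Ks (VA - RV)/(TLC - RV)) + Rsm`, so that
#' `Rs = Rsd + Rsm` at residual volume and `Rs ~ Rsm` at total lung
#' capacity.
#'
#' @param VA alveolar (lung) volume, ml.
#' @inheritParams upper_airway_resistance
#' @return Resistance, cm H2O.s/L.
#' @export
small_airway_resistance <- function(VA, params) {
  params$Rsd * exp(params$Ks * (VA - params$RV) / (params$TLC - params$RV)) +
    params$Rsm
}

#' Collapsible-airway pressure-volume curve and its inverse
#'
#' Sigmoidal curve `Vc = Vcmax / (1 + exp(-(Ptm - cc)/dc))` with maximal
#' compliance at the transmural pressure `cc`.  The inverse returns the
#' transmural pressure sustaining a given segment volume and is only
#' defined strictly inside `(0, Vcmax)`; callers integrating the ODE must
#' clamp first.
#'
#' @param Ptm transmural pressure across the airway wall, cm H2O.
#' @inheritParams upper_airway_resistance
#' @return Volume in ml (`collapsible_volume`) or pressure in cm H2O
#'   (`collapsible_pressure`).
#' @export
collapsible_volume <- function(Ptm, params) {
  params$Vcmax / (1 + exp(-(Ptm - params$cc) / params$dc))
}

#' @rdname collapsible_volume
#' @param Vc collapsible-airway volume, ml, strictly in `(0, Vcmax)`.
#' @export
collapsible_pressure <- function(Vc, params) {
  if (any(Vc <= 0 | Vc >= params$Vcmax))
    stop("Vc outside (0, Vcmax); clamp before inverting")
  params$cc - params$dc * log(params$Vcmax / Vc - 1)
}

#' Chest-wall pressure-volume curve (softplus) and its inverse
#'
#' `Vcw = RV + bw log(1 + exp((Pcw - cw)/dw))`: the smooth rectifier shape
#' observed in the undermineralised infant ribcage, with asymptote `RV` at
#' large negative recoil and slope `bw/dw` at large positive recoil.  The
#' curve passes through the relaxation volume `V0` at `Pcw = cw = 0`.
#'
#' @param Pcw chest-wall elastic recoil pressure, cm H2O.
#' @inheritParams upper_airway_resistance
#' @return Volume in ml (`chest_wall_volume`) or pressure in cm H2O
#'   (`chest_wall_pressure`).
#' @export
chest_wall_volume <- function(Pcw, params) {
  params$RV + params$bw * .softplus((Pcw - params$cw) / params$dw)
}

#' @rdname chest_wall_volume
#' @param Vcw chest-wall volume, ml, strictly greater than `RV`.
#' @export
chest_wall_pressure <- function(Vcw, params) {
  if (any(Vcw <= params$RV)) stop("Vcw must exceed RV")
  params$dw * .inv_softplus((Vcw - params$RV) / params$bw) + params$cw
}

#' Recruited fraction of alveoli
#'
#' Sigmoid in lung elastic recoil pressure,
#' `F_rec = alpha + (gamma - alpha)/(1 + exp(-(Pel - cF)/dF))`,
#' equal to `beta` at `Pel = 0` (by construction of `alpha`) and
#' approaching the ceiling `gamma` at high recoil.
#'
#' @param Pel lung elastic recoil pressure, cm H2O.
#' @param rec a [recruitment_state()] object.
#' @return Fraction recruited (dimensionless).
#' @export
recruited_fraction <- function(Pel, rec) {
  rec$alpha + (rec$gamma - rec$alpha) / (1 + exp(-(Pel - rec$cF) / rec$dF))
}

#' @rdname recruited_fraction
#' @details `recruited_fraction_deriv()` is the analytic
#'   `dF_rec/dPel`, used in the closed-form alveolar compliance.
#' @export
recruited_fraction_deriv <- function(Pel, rec) {
  e <- exp(-(Pel - rec$cF) / rec$dF)
  (rec$gamma - rec$alpha) * e / (rec$dF * (1 + e)^2)
}

#' Static lung volume and analytic alveolar compliance
#'
#' Lung volume is the product of the distension of recruited units,
#' `Vel = VC (1 - exp(-k Pel))`, and the recruited fraction, offset by
#' residual volume: `VA = Vel F_rec + RV`.  The alveolar compliance used in
#' the ODE system is the closed-form derivative
#' `CA = VC k e^{-k Pel} F_rec + VC (1 - e^{-k Pel}) F_rec'`.
#'
#' @param Pel lung elastic recoil pressure, cm H2O.
#' @inheritParams upper_airway_resistance
#' @param rec a [recruitment_state()] object.
#' @return Volume in ml (`lung_volume`) or compliance in ml/cm H2O
#'   (`alveolar_compliance`).
#' @examples
#' p <- resp_params(); r <- recruitment_state()
#' lung_volume(0, p, r)     # = RV
#' alveolar_compliance(0, p, r)  # = VC * k * beta
#' @export
lung_volume <- function(Pel, params, rec) {
  params$VC * (1 - exp(-params$k * Pel)) * recruited_fraction(Pel, rec) +
    params$RV
}

#' @rdname lung_volume
#' @export
alveolar_compliance <- function(Pel, params, rec) {
  ekp <- exp(-params$k * Pel)
  params$VC * params$k * ekp * recruited_fraction(Pel, rec) +
    params$VC * (1 - ekp) * recruited_fraction_deriv(Pel, rec)
}
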