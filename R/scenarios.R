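# Scenario registry (the 14 published simulations as named fixtures),
# flat-file configuration parsing and output writers.

# Table of condition-dependent constants: muscle amplitude per chest-wall
# condition and upper-airway state.  Braking multiplies the normal Ru
# coefficients tenfold during expiration only.
.amus_table <- list(high = c(normal = 1.85, increased = 3.2),
                    low  = c(normal = 2.78, increased = 3.8))
.dw_table <- c(high = 0.48, low = 2.4)

#' Scenario configuration
#'
#' Fully resolved configuration of a breath-by-breath simulation: the
#' chest-wall condition (which fixes `dw` and the default muscle
#' amplitude), the intervention (laryngeal braking or CPAP with its
#' recruited-fraction trigger), the permanent-closure fraction, frequency
#' policy, apnea, failure criterion and solver settings.
#'
#' @param name label carried through to outputs.
#' @param cw_condition `"high"` (floppy chest wall, `dw = 0.48`) or
#'   `"low"` (stiff, `dw = 2.4`).
#' @param braking apply the expiratory upper-airway resistance multiplier.
#' @param brake_multiplier multiplier for both Rohrer coefficients during
#'   expiration.
#' @param cpap_trigger recruited-fraction threshold activating CPAP
#'   (`NA` = never); the published runs use 0.90, 0.95, 0.97.
#' @param cpap_pressure airway-opening pressure once triggered, cm H2O.
#' @param permanent_fraction fraction of unrecruited alveoli permanently
#'   lost per breath (0 or 0.1 in the published runs).
#' @param frequency_mode `"constant"` or `"variable"` (rate follows the
#'   minute-ventilation demand).
#' @param apnea insert a single apneic event.
#' @param apnea_start,apnea_duration apnea timing, s.
#' @param A_mus muscle amplitude, cm H2O; default from the published
#'   per-condition calibration table.
#' @param target_VE minute-ventilation target, ml/min.
#' @param failure_fraction fraction of initial tidal volume that must be
#'   lost to declare failure (0.9 = "90% volume loss").
#' @param drift_scaling recruitment-drift reading, see
#'   [pressure_scale_factor()].
#' @param f_init initial frequency, breaths/s; `f_cap` its ceiling.
#' @param f_cap frequency ceiling, breaths/s.
#' @param max_breaths simulation horizon.
#' @param n_points trace points per breath.
#' @param rtol,atol stiff-solver tolerances.
#' @param params optional [resp_params()] override; built from
#'   `cw_condition` when `NULL`.
#' @param rec optional initial [recruitment_state()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            cw_condition = c("high", "low"),
                            braking = FALSE, brake_multiplier = 10,
                            cpap_trigger = NA_real_, cpap_pressure = 5,
                            permanent_fraction = 0,
                            frequency_mode = c("constant", "variable"),
                            apnea = FALSE, apnea_start = 120,
                            apnea_duration = 20,
                            A_mus = NULL, target_VE = 360,
                            failure_fraction = 0.9,
                            drift_scaling = c("radius_ratio",
                                              "increase_ratio"),
                            f_init = 1, f_cap = 3,
                            max_breaths = 250000L, n_points = 51,
                            rtol = 1e-6, atol = 1e-8,
                            params = NULL, rec = NULL) {
  cw_condition <- match.arg(cw_condition)
  frequency_mode <- match.arg(frequency_mode)
  drift_scaling <- match.arg(drift_scaling)
  if (!is.na(cpap_trigger) && (cpap_trigger <= 0 || cpap_trigger >= 1))
    stop("configuration error: cpap_trigger must be in (0, 1)")
  if (permanent_fraction < 0 || permanent_fraction > 1)
    stop("configuration error: permanent_fraction must be in [0, 1]")
  if (is.null(params)) params <- resp_params(dw = .dw_table[[cw_condition]])
  if (is.null(rec)) rec <- recruitment_state()
  if (is.null(A_mus))
    A_mus <- .amus_table[[cw_condition]][[
      if (braking) "increased" else "normal"]]
  sc <- list(name = name, cw_condition = cw_condition,
             braking = braking, brake_multiplier = brake_multiplier,
             cpap_trigger = cpap_trigger, cpap_pressure = cpap_pressure,
             permanent_fraction = permanent_fraction,
             frequency_mode = frequency_mode,
             apnea = apnea, apnea_start = apnea_start,
             apnea_duration = apnea_duration,
             A_mus = A_mus, target_VE = target_VE,
             failure_fraction = failure_fraction,
             drift_scaling = drift_scaling,
             f_init = f_init, f_cap = f_cap,
             max_breaths = as.integer(max_breaths), n_points = n_points,
             rtol = rtol, atol = atol,
             params = params, rec = rec)
  class(sc) <- "scenario_config"
  sc
}

#' @export
print.scenario_config <- function(x, ...) {
  iv <- if (x$braking) sprintf("braking x%g", x$brake_multiplier)
        else if (!is.na(x$cpap_trigger))
          sprintf("CPAP %g at Frec < %.2f", x$cpap_pressure, x$cpap_trigger)
        else "none"
  cat(sprintf("Scenario %s: %s Cw, intervention %s, p = %g, %s f\n",
              x$name, x$cw_condition, iv, x$permanent_fraction,
              x$frequency_mode))
  invisible(x)
}

# registry grid: intervention x chest-wall condition x permanent closure,
# plus the two extra CPAP triggers under high Cw
.registry_spec <- list(
  S1  = list(cw = "low",  brk = FALSE, trig = NA,   p = 0),
  S2  = list(cw = "low",  brk = FALSE, trig = NA,   p = 0.1),
  S3  = list(cw = "high", brk = FALSE, trig = NA,   p = 0),
  S4  = list(cw = "high", brk = FALSE, trig = NA,   p = 0.1),
  S5  = list(cw = "low",  brk = TRUE,  trig = NA,   p = 0),
  S6  = list(cw = "low",  brk = TRUE,  trig = NA,   p = 0.1),
  S7  = list(cw = "high", brk = TRUE,  trig = NA,   p = 0),
  S8  = list(cw = "high", brk = TRUE,  trig = NA,   p = 0.1),
  S9  = list(cw = "low",  brk = FALSE, trig = 0.90, p = 0),
  S10 = list(cw = "low",  brk = FALSE, trig = 0.90, p = 0.1),
  S11 = list(cw = "high", brk = FALSE, trig = 0.90, p = 0),
  S12 = list(cw = "high", brk = FALSE, trig = 0.90, p = 0.1),
  S13 = list(cw = "high", brk = FALSE, trig = 0.95, p = 0),
  S14 = list(cw = "high", brk = FALSE, trig = 0.97, p = 0))

#' Names of the built-in scenarios
#'
#' `"S1"` to `"S14"`: the published simulation grid — interventions (none,
#' laryngeal braking, CPAP triggered at 10/5/3% recruitment loss) crossed
#' with chest-wall condition and permanent-closure assumption.
#'
#' @return Character vector of registry names.
#' @export
scenario_names <- function() names(.registry_spec)

#' Load a scenario by registry name or from a configuration file
#'
#' Registry names (`"S1"`..`"S14"`, see [scenario_names()]) resolve to the
#' published simulation grid; any other string is treated as a path to a
#' flat `key = value` configuration file whose keys are the arguments of
#' [scenario_config()].  Additional arguments override either source.
#'
#' @param name_or_path registry name or file path.
#' @param ... overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @examples
#' load_scenario("S3")
#' load_scenario("S14", frequency_mode = "variable")
#' @export
load_scenario <- function(name_or_path, ...) {
  overrides <- list(...)
  if (name_or_path %in% names(.registry_spec)) {
    s <- .registry_spec[[name_or_path]]
    args <- list(name = name_or_path, cw_condition = s$cw, braking = s$brk,
                 cpap_trigger = if (is.na(s$trig)) NA_real_ else s$trig,
                 permanent_fraction = s$p)
  } else if (file.exists(name_or_path)) {
    args <- .parse_config_file(name_or_path)
    if (is.null(args$name))
      args$name <- tools::file_path_sans_ext(basename(name_or_path))
  } else {
    stop("configuration error: unknown scenario '", name_or_path, "'")
  }
  args[names(overrides)] <- overrides
  do.call(scenario_config, args)
}

# flat "key = value" (or "key: value") file; '#' starts a comment
.parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3)
      stop("configuration error: cannot parse line '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    args[[key]] <-
      if (grepl("^(true|false)$", val, ignore.case = TRUE))
        tolower(val) == "true"
      else if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", val)) as.numeric(val)
      else if (val %in% c("NA", "")) NA_real_
      else val
  }
  args
}

#' Write simulation outputs to a directory
#'
#' Writes `breaths.csv` (the per-breath summary table), `result.json`
#' (time to failure, failure breath, intervention log and scenario
#' metadata) and, when traces were kept, `traces.csv` with the decimated
#' state tracings.  CSV uses a header row and '.' decimal separator.
#'
#' @param result a `resp_sim` from [run_simulation()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  bp <- file.path(dir, "breaths.csv")
  utils::write.csv(result$breaths, bp, row.names = FALSE)
  paths <- c(paths, bp)
  meta <- list(
    scenario = result$scenario$name,
    cw_condition = result$scenario$cw_condition,
    TTF_hours = result$TTF,
    failure_breath = result$failure_breath,
    censored_at_hours = result$censored_at,
    n_breaths = nrow(result$breaths),
    cpap_breath = result$interventions$cpap_breath,
    apnea_window = result$interventions$apnea_window,
    final_recruitment = result$final_rec[c("gamma", "cF", "dF", "alpha")])
  jp <- file.path(dir, "result.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  paths <- c(paths, jp)
  if (!is.null(result$traces)) {
    tr <- do.call(rbind, Map(function(b, d) cbind(breath = as.integer(b), d),
                             names(result$traces), result$traces))
    tp <- file.path(dir, "traces.csv")
    utils::write.csv(tr, tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
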