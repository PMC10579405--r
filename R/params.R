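#' Kinetic model parameters
#'
#' Builds the full parameter set of the co-culture kinetic model. Defaults are
#' the package's calibrated set, chosen to reproduce the study's printed
#' observables (peak viable densities, pH endpoints and peak timings) for the
#' six batch scenarios; every value can be overridden, and a complete set can
#' be loaded from YAML with [read_params()] so that an externally supplied
#' parameterisation replaces the defaults without code changes.
#'
#' Units: rates in 1/h, concentrations and half-saturation/inhibition
#' constants in mM, cell densities in cells/ul, yields `Y_*` in cells/ul per
#' mM, acid stoichiometries `p_*` in mM acid per mM substrate consumed,
#' `r_M` in mM per (cells/ul) per h, `c_pH` in pH units per mM total acid.
#'
#' @param ... name-value overrides of individual defaults.
#' @return An object of class `mucodyn_params` (a validated named list).
#' @export
#' @examples
#' p <- model_params(mu_bt_G = 0.6)
#' p$mu_bt_G
model_params <- function(...) {
  p <- list(
    ## maximum specific growth rates
    mu_bt_G = 0.56,   # BT fast mode on glucose+pyruvate
    mu_ri_G = 0.50,   # RI fast mode on glucose+pyruvate
    mu_bt_M = 0.033,  # BT slow mode on mucin sugars
    mu_ri_M = 0.0,    # retained for generality; RI mucin growth not modeled
    mu_ri_A = 0.020,  # RI slow mode on acetate+lactate
    ## half-saturation constants
    K_G = 0.4, K_M = 0.5, K_A = 2.0,
    ## cross-inhibition constants
    KI_M_ri = 0.40,   # mucin sugars inhibit RI growth on glucose
    KI_G_bt = 0.25,   # glucose inhibits BT growth on mucin sugars
    ## biomass yields (cells/ul per mM substrate)
    Y_bt_G = 8.0e4, Y_ri_G = 5.2e4, Y_bt_M = 6.0e4, Y_ri_A = 5.0e4,
    ## acid stoichiometries (mM acid per mM substrate consumed)
    p_A_bt = 1.5,    # acetate+lactate from BT glucose fermentation
    p_X_bt = 1.0,    # succinate+formate from BT glucose fermentation
    p_A_ri = 0.93,   # acetate+lactate from RI glucose fermentation
    p_Bu_ri = 0.40,  # butyrate from RI glucose fermentation
    p_Bu_A = 0.5,    # butyrate per mM acetate+lactate consumed in slow mode
    ## mucin-sugar release per attached viable cell
    r_M = 2.5e-6,
    ## fixed attached fractions of total cells
    f_att_bt = 0.33, f_att_ri = 0.25,
    ## growth-state switching
    k_switch_bt = 0.5, k_switch_ri = 0.35,
    theta_G = 0.5, theta_M = 0.4, switch_eps = 0.08,
    ## death rates
    d_bt = 0.032, d_ri = 0.032,
    ## pH coupling
    pH0 = 6.7, c_pH = 0.045, pH_floor = 4.0,
    pH_half_bt = 5.5, pH_half_ri = 4.8, n_pH = 16
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "mucodyn_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-numeric or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  pos <- c("mu_bt_G", "mu_ri_G", "mu_bt_M", "mu_ri_A", "K_G", "K_M", "K_A",
           "KI_M_ri", "KI_G_bt", "Y_bt_G", "Y_ri_G", "Y_bt_M", "Y_ri_A",
           "r_M", "k_switch_bt", "k_switch_ri", "theta_G", "theta_M",
           "switch_eps", "d_bt", "d_ri", "c_pH", "n_pH")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$f_att_bt <= 0 || p$f_att_bt >= 1 || p$f_att_ri <= 0 || p$f_att_ri >= 1)
    stop("attached fractions must lie in (0, 1)")
  if (p$pH_half_bt <= p$pH_half_ri)
    stop("pH_half_bt must exceed pH_half_ri (BT is the acid-sensitive species)")
  invisible(p)
}

#' Batch-culture scenario configuration
#'
#' Describes one batch experiment: which species are inoculated, whether
#' mucin beads are present, the horizon and the initial medium composition.
#' The default initial sugar pool corresponds to the glucose plus pyruvate
#' supplied by WC medium.
#'
#' @param species one of `"BT_mono"`, `"RI_mono"`, `"co"`.
#' @param mucin_present logical; are mucin beads present?
#' @param t_end simulation horizon in hours.
#' @param bt0,ri0 inoculum viable densities (cells/ul); a species absent from
#'   `species` must have (and defaults to) zero inoculum.
#' @param G0,A0,Bu0 initial lumped glucose+pyruvate, acetate+lactate and
#'   butyrate (mM).
#' @param ph_override optional fixed pH; when set, the medium pH is clamped to
#'   this value throughout (pH-preference experiments).
#' @return An object of class `mucodyn_scenario`.
#' @export
scenario_config <- function(species = c("BT_mono", "RI_mono", "co"),
                            mucin_present = FALSE,
                            t_end = 120,
                            bt0 = NULL, ri0 = NULL,
                            G0 = 15, A0 = 0, Bu0 = 0,
                            ph_override = NULL) {
  species <- match.arg(species)
  if (is.null(bt0)) bt0 <- if (species %in% c("BT_mono", "co")) 2e3 else 0
  if (is.null(ri0)) ri0 <- if (species %in% c("RI_mono", "co")) 2e3 else 0
  if (t_end <= 0) stop("t_end must be positive")
  if (G0 < 0 || A0 < 0 || Bu0 < 0) stop("initial concentrations must be >= 0")
  if (bt0 < 0 || ri0 < 0) stop("inoculum densities must be >= 0")
  if (species == "BT_mono" && ri0 > 0)
    stop("RI inoculum must be zero in a BT monoculture")
  if (species == "RI_mono" && bt0 > 0)
    stop("BT inoculum must be zero in an RI monoculture")
  if (!is.null(ph_override) && (ph_override < 0 || ph_override > 14))
    stop("ph_override outside [0, 14]")
  structure(list(species = species, mucin_present = isTRUE(mucin_present),
                 t_end = t_end, bt0 = bt0, ri0 = ri0,
                 G0 = G0, A0 = A0, Bu0 = Bu0, ph_override = ph_override),
            class = "mucodyn_scenario")
}

#' The six study scenarios
#'
#' The scenario bundle mirroring the study design: BT monoculture, RI
#' monoculture and co-culture, each in plain WC medium and in WC with mucin
#' beads.
#'
#' @param t_end horizon in hours for every scenario.
#' @return Named list of [scenario_config()] objects.
#' @export
default_scenarios <- function(t_end = 120) {
  list(
    bt_mono_wc    = scenario_config("BT_mono", FALSE, t_end),
    ri_mono_wc    = scenario_config("RI_mono", FALSE, t_end),
    co_wc         = scenario_config("co",      FALSE, t_end),
    bt_mono_mucin = scenario_config("BT_mono", TRUE,  t_end),
    ri_mono_mucin = scenario_config("RI_mono", TRUE,  t_end),
    co_mucin      = scenario_config("co",      TRUE,  t_end)
  )
}

#' Experimental sampling grid
#'
#' Sampling times used throughout the study: every 4 h for the first 48 h,
#' then every 12 h up to `t_end`.
#'
#' @param t_end horizon in hours (default 120).
#' @return Numeric vector of sampling times in hours, starting at 0.
#' @export
#' @examples
#' length(sampling_grid(120)) # 19 points
sampling_grid <- function(t_end = 120) {
  g <- c(seq(0, min(48, t_end), by = 4),
         if (t_end > 48) seq(60, t_end, by = 12))
  g[g <= t_end]
}

#' Read / write model parameters as YAML
#'
#' `write_params()` serialises a parameter set; `read_params()` loads one,
#' fills unspecified entries with the package defaults and validates the
#' result, so an external parameterisation can be swapped in from config.
#'
#' @param params a `mucodyn_params` object.
#' @param path file path.
#' @return `read_params()` returns a `mucodyn_params` object.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(model_params, vals)
}

#' @export
print.mucodyn_params <- function(x, ...) {
  cat("<mucodyn_params> ", length(x), " parameters\n", sep = "")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.mucodyn_scenario <- function(x, ...) {
  cat(sprintf("<mucodyn_scenario> %s | mucin %s | %g h | BT0 %g, RI0 %g cells/ul | G0 %g mM\n",
              x$species, if (x$mucin_present) "present" else "absent",
              x$t_end, x$bt0, x$ri0, x$G0))
  invisible(x)
}
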