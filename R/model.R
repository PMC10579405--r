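#' pH from the total acid pool
#'
#' The medium pH is taken to be fully determined by the summed concentration
#' of fermentation acids: pH = max(pH_floor, pH0 - c_pH * (A + Bu + X)).
#' The linear pH/total-acid relationship reflects the strong linear
#' association observed between pH and the sum of short-chain fatty acid
#' concentrations in the fermentations; the floor guards against unphysical
#' values under parameter exploration.
#'
#' @param A lumped acetate+lactate (mM).
#' @param Bu butyrate (mM).
#' @param Acid_other lumped succinate+formate (mM).
#' @param params a [model_params()] object.
#' @return pH value(s); vectorised over the acid arguments.
#' @export
#' @examples
#' ph_from_acids(0, 0, 0, model_params()) # 6.7, the fresh-medium pH
ph_from_acids <- function(A, Bu, Acid_other, params) {
  if (any(A < 0) || any(Bu < 0) || any(Acid_other < 0))
    stop("acid concentrations must be >= 0")
  pmax(params$pH_floor, params$pH0 - params$c_pH * (A + Bu + Acid_other))
}

#' pH growth factor
#'
#' Sigmoidal (Hill) modulation of growth by pH: close to 1 near the fresh
#' medium pH of 6.7, 0.5 at `pH_half` and approaching 0 well below it. BT is
#' the more acid-sensitive species, so `pH_half_bt > pH_half_ri`.
#'
#' @param pH pH value(s) in `[0, 14]`.
#' @param pH_half midpoint of the response.
#' @param n_pH Hill steepness.
#' @return Factor(s) in `[0, 1]`, strictly increasing in pH.
#' @export
ph_growth_factor <- function(pH, pH_half, n_pH) {
  if (any(pH < 0) || any(pH > 14)) stop("pH outside [0, 14]")
  pHn <- pH^n_pH
  pHn / (pHn + pH_half^n_pH)
}

## smooth low-substrate threshold: ~1 when S << theta, ~0 when S >> theta
.low_substrate <- function(S, theta, eps) 1 / (1 + exp((S - theta) / eps))

.state_names <- c("bt_fast", "bt_slow", "ri_fast", "ri_slow",
                  "bt_dead", "ri_dead", "G", "M", "A", "Bu", "Acid_other")

#' Right-hand side of the kinetic ODE system
#'
#' Derivatives of the eleven-dimensional state: per-species viable fast/slow
#' and inviable densities, lumped glucose+pyruvate (G), mucin sugars (M),
#' acetate+lactate (A), butyrate (Bu) and other acids (succinate+formate).
#' Mechanisms encoded: Monod growth of both species on G; BT slow-mode growth
#' on mucin sugars inhibited by glucose; RI growth on G inhibited by mucin
#' sugars; RI slow-mode growth on acetate+lactate producing butyrate; smooth
#' threshold switching of each species into its slow mode at low substrate
#' (for RI only when both G and M are low); acid production tied to substrate
#' consumption; pH computed algebraically from the acid sum, inhibiting
#' growth through species-specific Hill factors; death moving viable cells to
#' the inviable pool, for BT accelerated at low pH when no energy source
#' (G or M) remains. Mucin polymer itself is treated as inexhaustible: mucin
#' sugars are released in proportion to the attached viable cells of both
#' species whenever beads are present.
#'
#' @param t time (h); unused (autonomous system) but part of the deSolve
#'   signature.
#' @param state named state vector (see `mucodyn:::.state_names`).
#' @param params a [model_params()] object.
#' @param scenario a [scenario_config()] object.
#' @return List whose first element is the derivative vector, plus the
#'   instantaneous pH as an auxiliary variable (deSolve convention).
#' @export
culture_rhs <- function(t, state, params, scenario) {
  if (any(state < -1e-6))
    stop("negative state component(s): ",
         paste(names(state)[state < -1e-6], collapse = ", "))
  s <- pmax(state, 0)  # guard tiny integrator undershoot
  p <- params
  G <- s[["G"]]; M <- s[["M"]]; A <- s[["A"]]
  Bu <- s[["Bu"]]; X <- s[["Acid_other"]]

  pH <- if (!is.null(scenario$ph_override)) scenario$ph_override
        else ph_from_acids(A, Bu, X, p)
  phi_bt <- ph_growth_factor(pH, p$pH_half_bt, p$n_pH)
  phi_ri <- ph_growth_factor(pH, p$pH_half_ri, p$n_pH)

  satG <- G / (p$K_G + G)
  satM <- M / (p$K_M + M)
  satA <- A / (p$K_A + A)

  ## growth fluxes (cells/ul/h)
  grow_bt_f <- p$mu_bt_G * satG * phi_bt * s[["bt_fast"]]
  grow_bt_s <- p$mu_bt_M * satM * p$KI_G_bt / (p$KI_G_bt + G) * phi_bt *
    s[["bt_slow"]]
  grow_ri_f <- p$mu_ri_G * satG * p$KI_M_ri / (p$KI_M_ri + M) * phi_ri *
    s[["ri_fast"]]
  grow_ri_s <- p$mu_ri_A * satA * phi_ri * s[["ri_slow"]]
  if (!scenario$mucin_present) grow_bt_s <- 0 * grow_bt_s

  ## state switching fast -> slow (BT: low glucose; RI: low glucose AND low M)
  lowG <- .low_substrate(G, p$theta_G, p$switch_eps)
  lowM <- .low_substrate(M, p$theta_M, p$switch_eps)
  sw_bt <- p$k_switch_bt * lowG * s[["bt_fast"]]
  sw_ri <- p$k_switch_ri * lowG * lowM * s[["ri_fast"]]

  ## death (viable -> dead); BT death needs low pH AND no energy source
  energy_bt <- max(satG, if (scenario$mucin_present) satM else 0)
  death_bt_rate <- p$d_bt * (1 - phi_bt) * (1 - energy_bt)
  die_bt_f <- death_bt_rate * s[["bt_fast"]]
  die_bt_s <- death_bt_rate * s[["bt_slow"]]
  die_ri_f <- p$d_ri * s[["ri_fast"]]
  die_ri_s <- p$d_ri * s[["ri_slow"]]

  ## substrate consumption fluxes (mM/h)
  cons_G <- grow_bt_f / p$Y_bt_G + grow_ri_f / p$Y_ri_G
  cons_M <- grow_bt_s / p$Y_bt_M
  cons_A <- grow_ri_s / p$Y_ri_A

  ## mucin-sugar release by attached viable cells of both species; BT's
  ## hydrolysis is catabolite-repressed by glucose (its mucin-utilisation
  ## machinery is switched off while glucose is available), governed by the
  ## same constant that gates BT growth on mucin sugars
  rel_M <- if (scenario$mucin_present)
    p$r_M * (p$f_att_bt * (s[["bt_fast"]] + s[["bt_slow"]]) *
               p$KI_G_bt / (p$KI_G_bt + G) +
             p$f_att_ri * (s[["ri_fast"]] + s[["ri_slow"]]))
  else 0

  d <- c(
    bt_fast = grow_bt_f - sw_bt - die_bt_f,
    bt_slow = grow_bt_s + sw_bt - die_bt_s,
    ri_fast = grow_ri_f - sw_ri - die_ri_f,
    ri_slow = grow_ri_s + sw_ri - die_ri_s,
    bt_dead = die_bt_f + die_bt_s,
    ri_dead = die_ri_f + die_ri_s,
    G = -cons_G,
    M = rel_M - cons_M,
    A = p$p_A_bt * (grow_bt_f / p$Y_bt_G) +
        p$p_A_ri * (grow_ri_f / p$Y_ri_G) - cons_A,
    Bu = p$p_Bu_ri * (grow_ri_f / p$Y_ri_G) + p$p_Bu_A * cons_A,
    Acid_other = p$p_X_bt * (grow_bt_f / p$Y_bt_G)
  )
  list(d, pH = pH)
}

#' Simulate a batch-culture scenario
#'
#' Integrates the kinetic model with a stiff-capable solver (lsoda) and
#' returns the trajectory on the requested time grid, with per-state
#' densities, viable and total cell counts, the planktonic/attached split
#' from the fixed attached fractions, substrate pools and pH.
#'
#' @param scenario a [scenario_config()] object.
#' @param params a [model_params()] object.
#' @param t_grid strictly increasing time grid (h) starting at 0; default the
#'   experimental sampling grid, refined hourly for smooth peak detection.
#' @param atol,rtol integrator tolerances.
#' @return A data.frame of class `mucodyn_sim` with one row per time point,
#'   columns for every state, `pH`, `bt_viable`, `ri_viable`, `bt_total`,
#'   `ri_total` and per-species planktonic/attached viable densities. The
#'   scenario and parameters are attached as attributes.
#' @export
#' @examples
#' sim <- simulate_culture(scenario_config("BT_mono"), model_params())
#' max(sim$bt_viable)
simulate_culture <- function(scenario, params,
                             t_grid = seq(0, scenario$t_end, by = 1),
                             atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(scenario, "mucodyn_scenario"),
            inherits(params, "mucodyn_params"))
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 and be strictly increasing")
  y0 <- c(bt_fast = scenario$bt0, bt_slow = 0,
          ri_fast = scenario$ri0, ri_slow = 0,
          bt_dead = 0, ri_dead = 0,
          G = scenario$G0, M = 0, A = scenario$A0, Bu = scenario$Bu0,
          Acid_other = 0)
  out <- deSolve::lsoda(y0, t_grid, culture_rhs, parms = params,
                        scenario = scenario, atol = atol, rtol = rtol)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop("ODE integration failed (lsoda istate = ", istate,
         ") for scenario ", scenario$species,
         if (scenario$mucin_present) " with mucin" else "")
  if (nrow(out) < length(t_grid))
    stop("ODE integration stopped early at t = ", max(out[, 1]), " h")
  sim <- as.data.frame(out)
  names(sim)[1] <- "time_h"
  if (any(vapply(sim[.state_names], min, numeric(1)) < -1e-9))
    stop("integration produced negative state values beyond tolerance")
  sim[.state_names] <- lapply(sim[.state_names], pmax, 0)

  sim$bt_viable <- sim$bt_fast + sim$bt_slow
  sim$ri_viable <- sim$ri_fast + sim$ri_slow
  sim$bt_total <- sim$bt_viable + sim$bt_dead
  sim$ri_total <- sim$ri_viable + sim$ri_dead
  f_bt <- if (scenario$mucin_present) params$f_att_bt else 0
  f_ri <- if (scenario$mucin_present) params$f_att_ri else 0
  sim$bt_viable_planktonic <- (1 - f_bt) * sim$bt_viable
  sim$bt_viable_attached <- f_bt * sim$bt_viable
  sim$ri_viable_planktonic <- (1 - f_ri) * sim$ri_viable
  sim$ri_viable_attached <- f_ri * sim$ri_viable
  attr(sim, "scenario") <- scenario
  attr(sim, "params") <- params
  class(sim) <- c("mucodyn_sim", "data.frame")
  sim
}

#' Trajectory summaries
#'
#' `peak_density()` locates the maximum of a species' viable density (in a
#' chosen compartment) and its time; `ph_at()` interpolates the pH at a time;
#' `min_ph()` and `endpoint_ph()` summarise the pH trajectory.
#'
#' @param sim a `mucodyn_sim` data.frame.
#' @param species `"bt"` or `"ri"`.
#' @param compartment `"planktonic"`, `"attached"` or `"total"` (total =
#'   liquid + beads viable pool).
#' @return `peak_density()` returns `list(value, time_h)`; the pH helpers a
#'   single number.
#' @export
peak_density <- function(sim, species = c("bt", "ri"),
                         compartment = c("planktonic", "attached", "total")) {
  species <- match.arg(species)
  compartment <- match.arg(compartment)
  col <- if (compartment == "total") paste0(species, "_viable")
         else paste0(species, "_viable_", compartment)
  i <- which.max(sim[[col]])
  list(value = sim[[col]][i], time_h = sim$time_h[i])
}

#' @rdname peak_density
#' @param t time (h) at which to evaluate the pH.
#' @export
ph_at <- function(sim, t) stats::approx(sim$time_h, sim$pH, xout = t)$y

#' @rdname peak_density
#' @export
min_ph <- function(sim) min(sim$pH)

#' @rdname peak_density
#' @export
endpoint_ph <- function(sim) sim$pH[nrow(sim)]
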