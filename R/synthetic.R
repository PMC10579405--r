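#' Noise specification for synthetic fermentation time series
#'
#' Replicate-to-replicate scatter is emulated with multiplicative lognormal
#' noise on cell densities (a fixed coefficient of variation, the natural
#' error model for counts spanning orders of magnitude) and additive Gaussian
#' noise, truncated at zero, on metabolite concentrations and pH.
#'
#' @param count_cv coefficient of variation of the multiplicative count noise.
#' @param met_sd additive SD on metabolite concentrations (mM).
#' @param ph_sd additive SD on pH.
#' @param replicates number of biological replicates to draw.
#' @param seed integer seed.
#' @return An object of class `mucodyn_noise`.
#' @export
noise_spec <- function(count_cv = 0.1, met_sd = 0.3, ph_sd = 0.05,
                       replicates = 3, seed = 1) {
  if (count_cv < 0 || met_sd < 0 || ph_sd < 0) stop("noise magnitudes must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(count_cv = count_cv, met_sd = met_sd, ph_sd = ph_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "mucodyn_noise")
}

## tidy observation table drawn from a simulation: the quantities a sampling
## campaign would record (planktonic viable counts, metabolites, pH; attached
## counts when beads are present)
observe_sim <- function(sim, scenario) {
  t <- sim$time_h
  rows <- list(
    data.frame(time_h = t, variable = "bt_viable", compartment = "planktonic",
               value = sim$bt_viable_planktonic, units = "cells/ul"),
    data.frame(time_h = t, variable = "ri_viable", compartment = "planktonic",
               value = sim$ri_viable_planktonic, units = "cells/ul"),
    data.frame(time_h = t, variable = "G", compartment = "total",
               value = sim$G, units = "mM"),
    data.frame(time_h = t, variable = "A", compartment = "total",
               value = sim$A, units = "mM"),
    data.frame(time_h = t, variable = "Bu", compartment = "total",
               value = sim$Bu, units = "mM"),
    data.frame(time_h = t, variable = "Acid_other", compartment = "total",
               value = sim$Acid_other, units = "mM"),
    data.frame(time_h = t, variable = "pH", compartment = "total",
               value = sim$pH, units = "pH")
  )
  if (scenario$mucin_present) {
    rows <- c(rows, list(
      data.frame(time_h = t, variable = "bt_viable", compartment = "attached",
                 value = sim$bt_viable_attached, units = "cells/ul"),
      data.frame(time_h = t, variable = "ri_viable", compartment = "attached",
                 value = sim$ri_viable_attached, units = "cells/ul"),
      data.frame(time_h = t, variable = "M", compartment = "total",
                 value = sim$M, units = "mM")))
  }
  do.call(rbind, rows)
}

#' Generate noisy replicated fermentation time series
#'
#' Simulates a scenario on the experimental sampling grid (every 4 h up to
#' 48 h, every 12 h afterwards) and applies the [noise_spec()] error model
#' independently per replicate. The noise-free truth trajectory is returned
#' alongside the replicates so that downstream estimators can be checked
#' against it.
#'
#' @param params a [model_params()] object.
#' @param scenario a [scenario_config()] object.
#' @param noise a [noise_spec()] object.
#' @return List with elements `truth` (the `mucodyn_sim` trajectory on the
#'   sampling grid), `observations` (tidy data.frame: `replicate`, `time_h`,
#'   `variable`, `compartment`, `value`, `units`) and `scenario`.
#' @export
generate_timeseries <- function(params, scenario, noise = noise_spec()) {
  grid <- sampling_grid(scenario$t_end)
  sim <- simulate_culture(scenario, params, t_grid = grid)
  base <- observe_sim(sim, scenario)
  count_sdlog <- sqrt(log(1 + noise$count_cv^2))
  reps <- withr::with_seed(noise$seed, {
    lapply(seq_len(noise$replicates), function(r) {
      obs <- base
      is_count <- obs$units == "cells/ul"
      is_met <- obs$units == "mM"
      is_ph <- obs$units == "pH"
      n <- nrow(obs)
      fac <- exp(stats::rnorm(n, -count_sdlog^2 / 2, count_sdlog))
      obs$value[is_count] <- obs$value[is_count] * fac[is_count]
      obs$value[is_met] <- pmax(0, obs$value[is_met] +
                                  stats::rnorm(sum(is_met), 0, noise$met_sd))
      obs$value[is_ph] <- obs$value[is_ph] +
        stats::rnorm(sum(is_ph), 0, noise$ph_sd)
      obs$replicate <- r
      obs
    })
  })
  observations <- do.call(rbind, reps)
  observations <- observations[c("replicate", "time_h", "variable",
                                 "compartment", "value", "units")]
  list(truth = sim, observations = observations, scenario = scenario)
}

#' Population specification for synthetic flow-cytometry events
#'
#' Describes a mixture of event populations (live BT, live RI, inviable
#' cells, debris and blank/background) on four channels (FSC, SSC, FL_SG,
#' FL_PI). Channel intensities are multivariate lognormal: each population
#' has a mean vector and covariance on the log scale, mimicking the
#' right-skewed intensity distributions of cytometry data. The default
#' geometry places live cells high in SG and low in PI, inviable cells high
#' in PI, and debris/blank low in both, with the BT/RI scatter separation
#' expressed in within-population SD units so that classification difficulty
#' is controllable.
#'
#' @param fractions named fractions over
#'   `c("BT_live","RI_live","inviable","debris","blank")`; must sum to 1.
#' @param total_events number of events to draw.
#' @param separation_sd BT/RI separation in the scatter channels, in SD units.
#' @param sdlog within-population log-scale SD (common default for all
#'   channels).
#' @param seed integer seed.
#' @param means optional 5x4 matrix of log-scale channel means (rows =
#'   populations, columns = `FSC`,`SSC`,`FL_SG`,`FL_PI`) overriding the
#'   default geometry.
#' @param covs optional list of 4x4 log-scale covariance matrices per
#'   population; each must be positive definite.
#' @return An object of class `mucodyn_popspec`.
#' @export
population_spec <- function(fractions = c(BT_live = 0.35, RI_live = 0.35,
                                          inviable = 0.1, debris = 0.1,
                                          blank = 0.1),
                            total_events = 10000, separation_sd = 6,
                            sdlog = 0.35, seed = 1,
                            means = NULL, covs = NULL) {
  pops <- c("BT_live", "RI_live", "inviable", "debris", "blank")
  if (!setequal(names(fractions), pops))
    stop("fractions must be named over: ", paste(pops, collapse = ", "))
  fractions <- fractions[pops]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be >= 0 and sum to 1")
  chans <- c("FSC", "SSC", "FL_SG", "FL_PI")
  if (is.null(means)) {
    sep <- separation_sd * sdlog / sqrt(2)  # split across FSC and SSC
    means <- rbind(
      BT_live  = c(log(3e4) + sep / 2, log(1e4) + sep / 2, log(5e4), log(2e2)),
      RI_live  = c(log(3e4) - sep / 2, log(1e4) - sep / 2, log(5e4), log(2e2)),
      inviable = c(log(2e4),           log(8e3),           log(8e3), log(3e4)),
      debris   = c(log(6e3),           log(3e3),           log(4e2), log(1.5e2)),
      blank    = c(log(1e3),           log(5e2),           log(8e1), log(5e1)))
    colnames(means) <- chans
  }
  means <- as.matrix(means)
  if (!identical(dim(means), c(5L, 4L))) stop("means must be a 5x4 matrix")
  rownames(means) <- pops; colnames(means) <- chans
  if (is.null(covs))
    covs <- stats::setNames(rep(list(diag(sdlog^2, 4)), 5), pops)
  for (nm in pops) {
    ev <- eigen(covs[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop("covariance for population ", nm, " is not positive definite")
  }
  structure(list(fractions = fractions, total_events = as.integer(total_events),
                 separation_sd = separation_sd, sdlog = sdlog,
                 seed = as.integer(seed), means = means, covs = covs,
                 channels = chans),
            class = "mucodyn_popspec")
}

#' Generate labeled synthetic flow-cytometry events
#'
#' Draws events from the mixture described by a [population_spec()]:
#' population membership is multinomial, channel intensities multivariate
#' lognormal. Ground-truth labels are retained for oracle-based testing of
#' the classification pipeline.
#'
#' @param pop a [population_spec()] object.
#' @param dilution dilution factor of the acquired sample (10 or 200 in the
#'   study design).
#' @param acquisition_volume_ul acquired volume in ul (1 min at 10 ul/min).
#' @param sample_id sample identifier stored on the table.
#' @return A data.frame (class `mucodyn_events`) with columns `event_id`,
#'   the four channels, `truth_label`, plus `sample_id`, `dilution` and
#'   `acquisition_volume_ul` attached as attributes and columns.
#' @export
generate_flow_events <- function(pop, dilution = 200,
                                 acquisition_volume_ul = 10,
                                 sample_id = "synthetic") {
  stopifnot(inherits(pop, "mucodyn_popspec"))
  withr::with_seed(pop$seed, {
    labels <- sample(names(pop$fractions), pop$total_events, replace = TRUE,
                     prob = pop$fractions)
    X <- matrix(NA_real_, pop$total_events, 4,
                dimnames = list(NULL, pop$channels))
    for (nm in unique(labels)) {
      idx <- which(labels == nm)
      X[idx, ] <- exp(MASS::mvrnorm(length(idx), pop$means[nm, ],
                                    pop$covs[[nm]]))
    }
    ev <- data.frame(event_id = seq_len(pop$total_events), X,
                     truth_label = labels,
                     sample_id = sample_id, dilution = dilution,
                     acquisition_volume_ul = acquisition_volume_ul)
    class(ev) <- c("mucodyn_events", "data.frame")
    ev
  })
}
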