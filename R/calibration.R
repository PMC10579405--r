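#' Specification of a calibration run
#'
#' Names the free parameters with their (positive, finite) box bounds, fixes
#' the rest, and sets the loss weights of the three observation blocks:
#' log10 viable densities, metabolite concentrations (mM) and pH.
#'
#' @param free named list of `c(lower, upper)` bounds per free parameter.
#' @param fixed_params a [model_params()] object supplying every other
#'   parameter.
#' @param weights named weights `c(count=, metabolite=, ph=)`; all >= 0, at
#'   least one positive.
#' @param n_starts Latin-hypercube starts of the global stage.
#' @param max_evals budget of objective evaluations per local refinement.
#' @param seed integer seed.
#' @return An object of class `mucodyn_fitspec`.
#' @export
fit_spec <- function(free, fixed_params = model_params(),
                     weights = c(count = 1, metabolite = 0.02, ph = 1),
                     n_starts = 8, max_evals = 200, seed = 1) {
  if (!length(free) || is.null(names(free)))
    stop("free must be a named list of bounds")
  unknown <- setdiff(names(free), names(fixed_params))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      stop("bounds for ", nm, " must be finite, positive and increasing")
  }
  if (any(weights < 0) || !any(weights > 0))
    stop("weights must be >= 0 with at least one > 0")
  structure(list(free = free, fixed_params = fixed_params, weights = weights,
                 n_starts = as.integer(n_starts),
                 max_evals = as.integer(max_evals), seed = as.integer(seed)),
            class = "mucodyn_fitspec")
}

params_with <- function(spec, theta) {
  vals <- as.list(unclass(spec$fixed_params))
  vals[names(spec$free)] <- as.list(theta)
  do.call(model_params, vals)
}

#' Calibration loss
#'
#' Weighted sum of squared residuals between observed tidy time series and
#' the model simulated at `params` under the same scenarios: viable-count
#' residuals on the log10(x + 1) scale (densities span four orders of
#' magnitude), metabolite residuals in mM, pH residuals in pH units.
#' Missing observations are skipped; a failed simulation yields `Inf`.
#'
#' @param params a [model_params()] object (or named vector of free values
#'   interpreted against `spec`).
#' @param observed named list over scenarios: each element a tidy
#'   observation table (`time_h`, `variable`, `compartment`, `value`,
#'   `units`) as produced by [generate_timeseries()].
#' @param scenarios named list of [scenario_config()] matching `observed`.
#' @param spec a [fit_spec()] object (for the weights).
#' @return Scalar loss >= 0.
#' @export
ts_loss <- function(params, observed, scenarios, spec) {
  if (!inherits(params, "mucodyn_params"))
    params <- params_with(spec, params)
  w <- spec$weights
  total <- 0
  for (nm in names(observed)) {
    obs <- observed[[nm]]
    sim <- try(simulate_culture(scenarios[[nm]], params,
                                t_grid = sort(unique(c(0, obs$time_h)))),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(Inf)
    pred <- observe_sim(sim, scenarios[[nm]])
    keyo <- paste(obs$time_h, obs$variable, obs$compartment)
    keyp <- paste(pred$time_h, pred$variable, pred$compartment)
    m <- match(keyo, keyp)
    ok <- !is.na(m) & !is.na(obs$value)
    po <- obs[ok, ]; pv <- pred$value[m[ok]]
    cnt <- po$units == "cells/ul"
    met <- po$units == "mM"
    ph <- po$units == "pH"
    total <- total +
      w["count"] * sum((log10(po$value[cnt] + 1) - log10(pv[cnt] + 1))^2) +
      w["metabolite"] * sum((po$value[met] - pv[met])^2) +
      w["ph"] * sum((po$value[ph] - pv[ph])^2)
  }
  unname(total)
}

#' Fit model parameters to observed time series
#'
#' Bounded global search (Latin-hypercube multistart over log-scaled
#' parameter boxes) followed by local refinement with `nlminb`, minimising
#' [ts_loss()]. All scenarios are fitted jointly with one shared parameter
#' set, mirroring the study design in which a single parameterisation
#' generates every culture condition.
#'
#' @param observed,scenarios as in [ts_loss()].
#' @param spec a [fit_spec()] object.
#' @return List with `params` (fitted [model_params()]), `theta` (free
#'   values), `loss`, `initial_loss` (at the best start), `converged`,
#'   `trace` (accepted-iterate losses of the winning start) and `residuals`.
#' @export
fit_params <- function(observed, scenarios, spec) {
  d <- length(spec$free)
  lower <- log(vapply(spec$free, `[`, numeric(1), 1))
  upper <- log(vapply(spec$free, `[`, numeric(1), 2))
  trace_env <- new.env()
  obj <- function(lt) {
    v <- ts_loss(stats::setNames(exp(lt), names(spec$free)),
                 observed, scenarios, spec)
    if (!is.finite(v)) v <- 1e10
    tr <- get0("tr", trace_env, ifnotfound = numeric(0))
    if (!length(tr) || v < min(tr)) assign("tr", c(tr, v), trace_env)
    v
  }
  starts <- withr::with_seed(spec$seed, lhs::randomLHS(spec$n_starts, d))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  best <- NULL
  for (s in seq_len(spec$n_starts)) {
    assign("tr", numeric(0), trace_env)
    fit <- try(stats::nlminb(starts[s, ], obj, lower = lower, upper = upper,
                             control = list(eval.max = spec$max_evals,
                                            iter.max = spec$max_evals)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$trace <- get("tr", trace_env)
      best$start <- starts[s, ]
    }
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("calibration failed: no start produced a finite loss")
  theta <- stats::setNames(exp(best$par), names(spec$free))
  params <- params_with(spec, theta)
  resid <- residual_table(params, observed, scenarios)
  list(params = params, theta = theta, loss = best$objective,
       initial_loss = obj(best$start), converged = best$convergence == 0,
       trace = best$trace, residuals = resid)
}

residual_table <- function(params, observed, scenarios) {
  out <- list()
  for (nm in names(observed)) {
    obs <- observed[[nm]]
    sim <- simulate_culture(scenarios[[nm]], params,
                            t_grid = sort(unique(c(0, obs$time_h))))
    pred <- observe_sim(sim, scenarios[[nm]])
    m <- match(paste(obs$time_h, obs$variable, obs$compartment),
               paste(pred$time_h, pred$variable, pred$compartment))
    out[[nm]] <- data.frame(scenario = nm, obs[c("time_h", "variable",
                                                 "compartment", "value")],
                            predicted = pred$value[m],
                            residual = obs$value - pred$value[m])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
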