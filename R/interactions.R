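#' Time-resolved interaction strength
#'
#' The impact of one species on the other, quantified as the log ratio of
#' its viable planktonic density in co-culture versus monoculture at each
#' time point: s(t) = log(co(t) / mono(t)). Positive values mean the partner
#' promotes the species, negative values competition. Time grids are aligned
#' by nearest-neighbour matching within a tolerance, else by linear
#' interpolation of log densities; points where the monoculture count is
#' zero (or negative) are flagged undefined rather than imputed.
#'
#' @param co,mono either `mucodyn_sim` trajectories or data.frames with
#'   `time_h` and a density column for the species.
#' @param species `"bt"` or `"ri"`.
#' @param base logarithm base: `exp(1)` (default), 2 or 10.
#' @param match_tol_h nearest-neighbour time-matching tolerance (h).
#' @return Data.frame `time_h`, `co`, `mono`, `strength`, `undefined`, with
#'   the log base recorded in the `"log_base"` attribute.
#' @export
#' @examples
#' t <- 0:10
#' co <- data.frame(time_h = t, bt_viable_planktonic = 2 * exp(0.3 * t))
#' mono <- data.frame(time_h = t, bt_viable_planktonic = exp(0.3 * t))
#' interaction_strength(co, mono, "bt")$strength[1] # log(2)
interaction_strength <- function(co, mono, species = c("bt", "ri"),
                                 base = exp(1), match_tol_h = 2) {
  species <- match.arg(species)
  col <- paste0(species, "_viable_planktonic")
  get_series <- function(x) {
    if (!col %in% names(x))
      stop("input lacks column ", col)
    data.frame(time_h = x$time_h, value = x[[col]])
  }
  s_co <- get_series(co)
  s_mono <- get_series(mono)
  mono_at <- vapply(s_co$time_h, function(t) {
    i <- which.min(abs(s_mono$time_h - t))
    if (abs(s_mono$time_h[i] - t) <= match_tol_h) return(s_mono$value[i])
    if (t < min(s_mono$time_h) || t > max(s_mono$time_h)) return(NA_real_)
    ## interpolate on the log scale, where growth is near-linear
    exp(stats::approx(s_mono$time_h, log(pmax(s_mono$value, 1e-12)),
                      xout = t)$y)
  }, numeric(1))
  undefined <- !is.finite(mono_at) | mono_at <= 0 | s_co$value <= 0
  strength <- rep(NA_real_, nrow(s_co))
  strength[!undefined] <- log(s_co$value[!undefined] / mono_at[!undefined]) /
    log(base)
  out <- data.frame(time_h = s_co$time_h, co = s_co$value, mono = mono_at,
                    strength = strength, undefined = undefined)
  attr(out, "log_base") <- base
  out
}

#' Linear pH vs total-SCFA relationship
#'
#' Ordinary least squares of pH on the summed acid concentration. On
#' study-like data the slope is negative: each mM of accumulated acid
#' depresses the pH by a fixed amount, which is the empirical basis of the
#' model's algebraic pH coupling.
#'
#' @param ph pH observations.
#' @param scfa_sum paired total acid concentrations (mM).
#' @return List `slope`, `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
fit_ph_scfa <- function(ph, scfa_sum) {
  if (length(ph) != length(scfa_sum)) stop("inputs must be paired")
  ok <- is.finite(ph) & is.finite(scfa_sum)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  if (stats::sd(scfa_sum[ok]) == 0)
    stop("degenerate regression: constant SCFA sum")
  fit <- stats::lm(ph[ok] ~ scfa_sum[ok])
  sm <- suppressWarnings(summary(fit))  # exact lines trip the perfect-fit warning
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       slope_se = sm$coefficients[2, 2],
       n = sum(ok))
}

#' Linearity of attached vs planktonic viable counts
#'
#' Regression of attached on planktonic viable densities. Under the model's
#' fixed attached fraction f, the two are exactly proportional with slope
#' f / (1 - f); a high R-squared on observed data supports that assumption.
#'
#' @param attached,planktonic paired viable densities (cells/ul).
#' @param through_origin fit without an intercept (default `TRUE`, matching
#'   the proportionality hypothesis).
#' @return List `slope`, `intercept` (0 when through the origin),
#'   `r_squared`, `n`.
#' @export
attachment_linearity <- function(attached, planktonic, through_origin = TRUE) {
  if (length(attached) != length(planktonic)) stop("inputs must be paired")
  ok <- is.finite(attached) & is.finite(planktonic)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  if (stats::sd(planktonic[ok]) == 0)
    stop("degenerate regression: constant planktonic counts")
  a <- attached[ok]; p <- planktonic[ok]
  if (through_origin) {
    fit <- stats::lm(a ~ p - 1)
    slope <- unname(stats::coef(fit)[1])
    ## R^2 about the mean (comparable to the intercept fit)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((a - mean(a))^2)
    list(slope = slope, intercept = 0, r_squared = r2, n = length(a))
  } else {
    fit <- stats::lm(a ~ p)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = length(a))
  }
}
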