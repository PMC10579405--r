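test_that("pH follows the acid sum linearly down to the floor", {
  p <- default_params
  expect_equal(ph_from_acids(0, 0, 0, p), 6.7)
  ## linearity: doubling total acid doubles the drop below pH0
  drop1 <- p$pH0 - ph_from_acids(5, 3, 2, p)
  drop2 <- p$pH0 - ph_from_acids(10, 6, 4, p)
  expect_equal(drop2, 2 * drop1)
  ## monotone non-increasing in each acid, floored at pH_floor
  expect_true(ph_from_acids(6, 0, 0, p) <= ph_from_acids(5, 0, 0, p))
  expect_equal(ph_from_acids(500, 0, 0, p), p$pH_floor)
  expect_error(ph_from_acids(-1, 0, 0, p), "acid")
})

test_that("pH growth factor is a Hill curve separating the two species", {
  p <- default_params
  ## midpoint identity and monotonicity
  expect_equal(ph_growth_factor(p$pH_half_bt, p$pH_half_bt, p$n_pH), 0.5)
  grid <- seq(4, 7, by = 0.1)
  f <- ph_growth_factor(grid, p$pH_half_bt, p$n_pH)
  expect_true(all(diff(f) > 0))
  ## BT grows normally at the fresh-medium pH but not at pH 4.5
  expect_gte(ph_growth_factor(6.7, p$pH_half_bt, p$n_pH), 0.95)
  expect_lte(ph_growth_factor(4.5, p$pH_half_bt, p$n_pH), 0.05)
  ## RI tolerates pH 5.3 far better than BT (acid-sensitivity ordering)
  expect_gt(ph_growth_factor(5.3, p$pH_half_ri, p$n_pH),
            ph_growth_factor(5.3, p$pH_half_bt, p$n_pH))
  expect_error(ph_growth_factor(-1, 5.5, 16), "pH")
})

test_that("rhs is zero without biomass and gates mucin terms by scenario", {
  p <- default_params
  sc <- scenario_config("co", mucin_present = FALSE)
  s0 <- c(bt_fast = 0, bt_slow = 0, ri_fast = 0, ri_slow = 0, bt_dead = 0,
          ri_dead = 0, G = 15, M = 0, A = 0, Bu = 0, Acid_other = 0)
  d <- culture_rhs(0, s0, p, sc)[[1]]
  expect_true(all(d == 0))
  ## mucin absent: no release even with cells present
  s1 <- s0; s1["bt_fast"] <- 1e4; s1["ri_fast"] <- 1e4
  expect_equal(culture_rhs(0, s1, p, sc)[[1]][["M"]], 0)
  sc_m <- scenario_config("co", mucin_present = TRUE)
  expect_gt(culture_rhs(0, s1, p, sc_m)[[1]][["M"]], 0)
  expect_error(culture_rhs(0, replace(s1, "G", -1), p, sc), "negative")
})

test_that("per-capita BT growth approaches mu_bt_G in the Monod limit", {
  ## saturating glucose, fresh pH, single fast population: the specific
  ## growth rate must match the symbolic limit mu * G/(K+G) * phi(pH)
  p <- model_params(d_bt = 1e-12)  # death off: isolate the growth term
  sc <- scenario_config("BT_mono", G0 = 1000)
  s <- c(bt_fast = 1e3, bt_slow = 0, ri_fast = 0, ri_slow = 0, bt_dead = 0,
         ri_dead = 0, G = 1000, M = 0, A = 0, Bu = 0, Acid_other = 0)
  d <- culture_rhs(0, s, p, sc)[[1]]
  expected <- p$mu_bt_G * (1000 / (p$K_G + 1000)) *
    ph_growth_factor(6.7, p$pH_half_bt, p$n_pH)
  expect_equal(d[["bt_fast"]] / 1e3, expected, tolerance = 1e-12)
  expect_lt(abs(d[["bt_fast"]] / 1e3 - p$mu_bt_G) / p$mu_bt_G, 0.05)
})

test_that("simulation conserves cells, keeps states non-negative, dead monotone", {
  for (nm in c("bt_mono_wc", "ri_mono_wc", "co_wc", "co_mucin")) {
    sim <- fast_sim(nm)
    states <- as.matrix(sim[mucodyn:::.state_names])
    expect_true(all(states >= -1e-9), label = paste(nm, "non-negativity"))
    expect_true(all(diff(sim$bt_dead) >= -1e-9), label = paste(nm, "bt_dead"))
    expect_true(all(diff(sim$ri_dead) >= -1e-9), label = paste(nm, "ri_dead"))
    ## switching and death conserve totals: total change equals net growth,
    ## so per-species total never exceeds inoculum + yield * substrate used
    sc <- attr(sim, "scenario")
    expect_equal(sim$bt_total, sim$bt_fast + sim$bt_slow + sim$bt_dead)
  }
})

test_that("zero inoculum is absorbing: no growth, substrate untouched", {
  sc <- scenario_config("BT_mono", bt0 = 0, t_end = 48)
  sim <- simulate_culture(sc, default_params, t_grid = seq(0, 48, 4))
  expect_true(all(sim$bt_total == 0))
  expect_true(all(sim$G == sc$G0))
  expect_true(all(sim$pH == 6.7))
})

test_that("reduced Monod batch model matches a fine-grid reference integration", {
  ## single species, no switching, no death: compare lsoda on the test grid
  ## against an independent fixed-step RK4 integration at dt = 0.002 h
  p <- model_params(d_bt = 1e-12, k_switch_bt = 1e-12, k_switch_ri = 1e-12,
                    d_ri = 1e-12, p_A_bt = 1e-12, p_X_bt = 1e-12)
  ## acids off so pH stays 6.7 and the system is pure Monod batch growth
  sc <- scenario_config("BT_mono", t_end = 24)
  grid <- seq(0, 24, by = 2)
  sim <- simulate_culture(sc, p, t_grid = grid)
  mu <- p$mu_bt_G * ph_growth_factor(6.7, p$pH_half_bt, p$n_pH)
  deriv <- function(y) {
    s <- y[1] * (y[2] / (p$K_G + y[2]))
    c(mu * s, -mu * s / p$Y_bt_G)
  }
  y <- c(sc$bt0, sc$G0)
  dt <- 0.002
  ref <- matrix(NA_real_, length(grid), 2)
  ref[1, ] <- y
  ti <- 0
  for (i in 2:length(grid)) {
    while (ti < grid[i] - 1e-9) {
      k1 <- deriv(y); k2 <- deriv(y + dt / 2 * k1)
      k3 <- deriv(y + dt / 2 * k2); k4 <- deriv(y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      ti <- ti + dt
    }
    ref[i, ] <- y
  }
  expect_lt(max(abs(sim$bt_fast - ref[, 1]) / pmax(ref[, 1], 1)), 1e-3)
  expect_lt(max(abs(sim$G - ref[, 2]) / pmax(ref[, 2], 1e-3)), 1e-3)
})

test_that("pH is monotone non-increasing without acid consumption and rises in slow mode", {
  ## RI slow mode disabled: no acid sink, pH can only fall
  p_off <- model_params(mu_ri_A = 1e-12)
  sim_off <- simulate_culture(default_scenarios(120)$ri_mono_wc, p_off,
                              t_grid = seq(0, 120, 2))
  expect_true(all(diff(sim_off$pH) <= 1e-9))
  ## acid-rich glucose-free start with RI in slow mode raises the pH
  sc <- scenario_config("RI_mono", G0 = 0.01, A0 = 20, t_end = 48)
  sim <- simulate_culture(sc, default_params, t_grid = seq(0, 48, 2))
  expect_gt(endpoint_ph(sim), sim$pH[1])
  expect_gt(max(sim$Bu) , 0)  # butyrate produced from the consumed acids
})

test_that("mucin shifts the co-culture peaks in the observed directions", {
  co_wc <- fast_sim("co_wc")
  co_mu <- fast_sim("co_mucin")
  expect_gt(peak_density(co_mu, "bt", "planktonic")$value,
            peak_density(co_wc, "bt", "planktonic")$value)
  expect_lt(peak_density(co_mu, "ri", "planktonic")$value,
            peak_density(co_wc, "ri", "planktonic")$value)
})

test_that("scenario and parameter validation reject inconsistent input", {
  expect_error(scenario_config("BT_mono", ri0 = 10), "RI inoculum")
  expect_error(scenario_config("co", t_end = -1), "t_end")
  expect_error(model_params(mu_bt_G = -1), "positive")
  expect_error(model_params(pH_half_bt = 4, pH_half_ri = 5), "acid-sensitive")
  expect_error(model_params(bogus = 1), "unknown")
  expect_error(simulate_culture(scenario_config("BT_mono"), default_params,
                                t_grid = c(1, 2)), "t_grid")
})

test_that("parameter sets round-trip through YAML", {
  p <- model_params(mu_bt_G = 0.61, r_M = 3e-6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  p2 <- read_params(path)
  expect_equal(unclass(p2), unclass(p))
})
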