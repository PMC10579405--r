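test_that("sampling grid matches the study design", {
  g <- sampling_grid(120)
  expect_length(g, 19)  # 13 points 0-48 h step 4, then 60-120 h step 12
  expect_equal(g[1:4], c(0, 4, 8, 12))
  expect_equal(tail(g, 3), c(96, 108, 120))
  expect_equal(sampling_grid(48), seq(0, 48, 4))
})

test_that("time-series generator is exact at zero noise and seed-stable", {
  sc <- default_scenarios(48)$bt_mono_wc
  clean <- generate_timeseries(default_params, sc,
                               noise_spec(0, 0, 0, replicates = 2, seed = 3))
  truth_tab <- mucodyn:::observe_sim(clean$truth, sc)
  for (r in 1:2) {
    rep_r <- clean$observations[clean$observations$replicate == r, ]
    expect_equal(rep_r$value, truth_tab$value)
  }
  n1 <- generate_timeseries(default_params, sc,
                            noise_spec(0.2, 0.5, 0.05, 3, seed = 7))
  n2 <- generate_timeseries(default_params, sc,
                            noise_spec(0.2, 0.5, 0.05, 3, seed = 7))
  expect_identical(n1$observations, n2$observations)
  ## noise respects non-negativity of concentrations
  mets <- n1$observations$units == "mM"
  expect_true(all(n1$observations$value[mets] >= 0))
})

test_that("count noise has the specified coefficient of variation", {
  sc <- default_scenarios(48)$bt_mono_wc
  gen <- generate_timeseries(default_params, sc,
                             noise_spec(0.15, 0, 0, replicates = 200,
                                        seed = 5))
  obs <- gen$observations
  counts <- obs[obs$variable == "bt_viable" & obs$time_h == 24, ]
  truth <- mucodyn:::observe_sim(gen$truth, sc)
  mu <- truth$value[truth$variable == "bt_viable" & truth$time_h == 24]
  expect_equal(mean(counts$value) / mu, 1, tolerance = 0.05)
  expect_equal(stats::sd(counts$value) / mean(counts$value), 0.15,
               tolerance = 0.2)
})

test_that("event generator honours fractions, means and label bookkeeping", {
  pop <- population_spec(fractions = c(BT_live = 0.5, RI_live = 0.5,
                                       inviable = 0, debris = 0, blank = 0),
                         total_events = 10000, seed = 13)
  ev <- generate_flow_events(pop)
  n_bt <- sum(ev$truth_label == "BT_live")
  ## multinomial tolerance: 5000 +- 4 binomial SDs (= 200)
  expect_lt(abs(n_bt - 5000), 200)
  ## empirical log-channel means within 3 SE of the specification
  for (nm in c("BT_live", "RI_live")) {
    sub <- log(as.matrix(ev[ev$truth_label == nm, flow_channels]))
    se <- pop$sdlog / sqrt(nrow(sub))
    expect_true(all(abs(colMeans(sub) - pop$means[nm, ]) < 3.5 * se))
  }
  ## determinism
  expect_identical(generate_flow_events(pop)$FSC, ev$FSC)
  expect_error(population_spec(fractions = c(BT_live = 2, RI_live = -1,
                                             inviable = 0, debris = 0,
                                             blank = 0)), "sum to 1")
  bad_cov <- replicate(5, diag(4) * 0, simplify = FALSE)
  names(bad_cov) <- c("BT_live", "RI_live", "inviable", "debris", "blank")
  expect_error(population_spec(covs = bad_cov), "positive definite")
})

test_that("a pure blank sample is flagged ~100% blank by the gate", {
  blank_only <- c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0,
                  blank = 1)
  ev <- generate_flow_events(population_spec(fractions = blank_only,
                                             total_events = 900, seed = 31))
  bl <- generate_flow_events(population_spec(fractions = blank_only,
                                             total_events = 900, seed = 32))
  ## stain channels are unimodal here, so thresholds must be supplied
  g <- gate_categories(ev, bl, sg_threshold = 10, pi_threshold = 10,
                       seed = 3)
  expect_gte(mean(g$events$category == "blank"), 0.95)
})

test_that("round-trip: pipeline recovers population fractions at 6-SD separation", {
  ev <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0.4, RI_live = 0.3, inviable = 0.15,
                  debris = 0.05, blank = 0.1),
    total_events = 3000, separation_sd = 6, seed = 44))
  blanks <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0,
                  blank = 1), total_events = 700, seed = 45))
  g <- gate_categories(ev, blanks, seed = 9)
  called <- table(g$events$category) / nrow(ev)
  truth_cat <- c(BT_live = "live", RI_live = "live", inviable = "inviable",
                 debris = "debris", blank = "blank")[ev$truth_label]
  truth_frac <- table(factor(truth_cat, names(called))) / nrow(ev)
  expect_true(all(abs(called - truth_frac) <= 0.02))
})
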