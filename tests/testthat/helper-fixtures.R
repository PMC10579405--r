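## shared fixtures: small, fast variants of the study objects
default_params <- model_params()

fast_sim <- function(scenario_name = "bt_mono_wc", t_end = 120,
                     params = default_params, by = 2) {
  sc <- default_scenarios(t_end)[[scenario_name]]
  simulate_culture(sc, params, t_grid = seq(0, t_end, by = by))
}

## single-population event tables
pure_events <- function(population, n = 1500, separation_sd = 6, seed = 1) {
  f <- c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0, blank = 0)
  f[population] <- 1
  generate_flow_events(population_spec(fractions = f, total_events = n,
                                       separation_sd = separation_sd,
                                       seed = seed))
}

flow_channels <- c("FSC", "SSC", "FL_SG", "FL_PI")
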