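#!/usr/bin/env Rscript
## Simulate the six batch-culture scenarios (BT mono, RI mono, co-culture,
## each without and with mucin beads) with the calibrated kinetic model and
## summarise the observables the study reports: peak viable densities and
## their timing, pH minima/endpoints, and attached-compartment maxima.
## Writes results/trajectories.csv (tidy) and results/scenario_summary.csv.

library(mucodyn)

dir.create("results", showWarnings = FALSE)
params <- model_params()
scenarios <- default_scenarios()

tidy <- list()
summary_rows <- list()
for (nm in names(scenarios)) {
  sc <- scenarios[[nm]]
  sim <- simulate_culture(sc, params)
  obs <- mucodyn:::observe_sim(sim, sc)
  obs$scenario <- nm
  tidy[[nm]] <- obs
  bt <- peak_density(sim, "bt", "planktonic")
  ri <- peak_density(sim, "ri", "planktonic")
  ba <- peak_density(sim, "bt", "attached")
  ra <- peak_density(sim, "ri", "attached")
  summary_rows[[nm]] <- data.frame(
    scenario = nm,
    bt_peak_cells_per_ul = bt$value, bt_peak_time_h = bt$time_h,
    ri_peak_cells_per_ul = ri$value, ri_peak_time_h = ri$time_h,
    bt_attached_max = ba$value, ri_attached_max = ra$value,
    ph_min = min_ph(sim), ph_24h = ph_at(sim, 24),
    ph_end = endpoint_ph(sim))
}
trajectories <- do.call(rbind, tidy)
write_timeseries(trajectories[c("time_h", "variable", "compartment",
                                "value", "units", "scenario")],
                 "results/trajectories.csv")
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/scenario_summary.csv", row.names = FALSE)

cat("Scenario summary (viable planktonic peaks, cells/ul; pH):\n")
print(summary, digits = 3, row.names = FALSE)
cat("\nKey observations reproduced by the calibrated model:\n")
cat(sprintf(" - BT WC monoculture peaks at %.2g cells/ul (t = %g h), endpoint pH %.2f\n",
            summary["bt_mono_wc", "bt_peak_cells_per_ul"],
            summary["bt_mono_wc", "bt_peak_time_h"],
            summary["bt_mono_wc", "ph_end"]))
cat(sprintf(" - RI WC monoculture peaks at %.2g cells/ul; pH %.2f at 24 h, rising to %.2f by 120 h (slow-mode acid consumption)\n",
            summary["ri_mono_wc", "ri_peak_cells_per_ul"],
            summary["ri_mono_wc", "ph_24h"], summary["ri_mono_wc", "ph_end"]))
cat(sprintf(" - Mucin raises the BT co-culture peak %.1f-fold (%.2g vs %.2g) and lowers RI's (%.2g vs %.2g)\n",
            summary["co_mucin", "bt_peak_cells_per_ul"] /
              summary["co_wc", "bt_peak_cells_per_ul"],
            summary["co_mucin", "bt_peak_cells_per_ul"],
            summary["co_wc", "bt_peak_cells_per_ul"],
            summary["co_mucin", "ri_peak_cells_per_ul"],
            summary["co_wc", "ri_peak_cells_per_ul"]))
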