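#!/usr/bin/env Rscript
## Run the flow-cytometry event-classification pipeline on synthetic
## mixtures with known composition: gating against a blank run, then
## supervised species assignment of co-culture live events at three
## BT/RI separations. Writes results/flow_counts.csv and
## results/flow_accuracy.csv.

library(mucodyn)

dir.create("results", showWarnings = FALSE)
chans <- c("FSC", "SSC", "FL_SG", "FL_PI")
seed <- 20

## --- gating on a five-population mixture -------------------------------
pop <- population_spec(total_events = 4000, separation_sd = 6, seed = seed)
ev <- generate_flow_events(pop, dilution = 200)
blanks <- generate_flow_events(
  population_spec(fractions = c(BT_live = 0, RI_live = 0, inviable = 0,
                                debris = 0.05, blank = 0.95),
                  total_events = 800, seed = seed + 1))
g <- gate_categories(ev, blanks, seed = seed)
truth_cat <- c(BT_live = "live", RI_live = "live", inviable = "inviable",
               debris = "debris", blank = "blank")[ev$truth_label]
gate_acc <- mean(truth_cat == as.character(g$events$category))
counts <- count_populations(g$events, dilution = 200,
                            acquisition_volume_ul = 10)
write.csv(counts, "results/flow_counts.csv", row.names = FALSE)
cat(sprintf("Gating at 6-SD separation: %.1f%% of %d events in the correct category\n",
            100 * gate_acc, nrow(ev)))
print(counts, row.names = FALSE)

## --- species assignment at increasing separation ------------------------
mono <- function(sp, sep, s) {
  f <- c(BT_live = 0, RI_live = 0, inviable = 0, debris = 0, blank = 0)
  f[sp] <- 1
  generate_flow_events(population_spec(fractions = f, total_events = 3000,
                                       separation_sd = sep, seed = s))
}
acc_rows <- lapply(c(2, 4, 6), function(sep) {
  bt_ref <- mono("BT_live", sep, seed + 2)
  ri_ref <- mono("RI_live", sep, seed + 3)
  co <- generate_flow_events(population_spec(
    fractions = c(BT_live = 0.5, RI_live = 0.5, inviable = 0, debris = 0,
                  blank = 0),
    total_events = 3000, separation_sd = sep, seed = seed + 4))
  cl <- classify_species(co, list(BT = bt_ref, RI = ri_ref),
                         n_training = 2500, seed = seed)
  truth <- ifelse(co$truth_label == "BT_live", "BT", "RI")
  data.frame(separation_sd = sep,
             accuracy = mean(cl$species == truth),
             bt_accuracy = mean(cl$species[truth == "BT"] == "BT"),
             ri_accuracy = mean(cl$species[truth == "RI"] == "RI"),
             mean_margin = mean(cl$margin))
})
acc <- do.call(rbind, acc_rows)
acc <- cbind(acc, gating_accuracy_6sd = gate_acc)
write.csv(acc, "results/flow_accuracy.csv", row.names = FALSE)
cat("\nSpecies-assignment accuracy vs BT/RI separation (SD units):\n")
print(acc, digits = 4, row.names = FALSE)
cat("\nAccuracy rises with separation; near-complete overlap (2 SD) is the",
    "regime the study flags as hard (live/inviable transitions).\n")
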