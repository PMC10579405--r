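# mucodyn

Kinetic modeling and flow-cytometry analysis of a mucin-bead gut bacterial
co-culture.

## The problem

*Bacteroides thetaiotaomicron* (BT) and *Roseburia intestinalis* (RI) are
two abundant human gut bacteria with opposite starvation strategies. In
batch culture both ferment the medium's glucose and pyruvate; BT acidifies
the medium so strongly (pH 6.7 → ~5.0) that it destroys its own viability
once sugar runs out, while RI survives by a diauxic shift into a slow
growth mode that converts acetate and lactate to butyrate, raising the pH
back up. Mucin beads — a stand-in for the gut's mucosal surfaces — flip the
outcome: BT forages on mucin-derived sugars and persists at low pH, while
free mucin sugars inhibit RI's growth on glucose. The net interaction
between the species therefore changes sign over time and with the
environment, which is exactly what makes constant-interaction population
models (e.g. generalized Lotka-Volterra) inadequate here.

`mucodyn` packages the computational side of this study for anyone who
wants to simulate, fit, or reanalyse such dynamics:

* a mechanistic ODE model of the co-culture (growth, death, state
  switching, acid-coupled pH, mucin release/consumption),
* a flow-cytometry event-classification pipeline (variance-stabilising
  normalisation, 3-D neighbour-graph embedding, live/inviable/debris/blank
  gating, blank-overlap removal, supervised BT/RI assignment),
* calibration with parameter-recovery diagnostics,
* interaction-strength analytics, and
* a synthetic-data generator that emulates both the fermentation time
  series and the cytometry event mixtures, so every stage is testable
  without the original raw data.

## The model in brief

Per species, viable cells split into a fast state growing on lumped
glucose+pyruvate *G* by Monod kinetics and a slow state (BT: growth on
mucin sugars *M*; RI: growth on acetate+lactate *A* with butyrate
production). Growth is scaled by a Hill factor in pH,
φ(pH) = pH<sup>n</sup>/(pH<sup>n</sup> + pH<sub>half</sub><sup>n</sup>),
with BT the more acid-sensitive species; pH itself is algebraic,
pH = max(4, 6.7 − c<sub>pH</sub>·ΣSCFA). Cells switch fast → slow through
smooth low-substrate thresholds σ(θ−S), die into an inviable pool (for BT
only when acid-stressed *and* energy-starved), and a fixed fraction of each
species (33% BT, 25% RI) is bead-attached; attached viable cells release
mucin sugars, BT's release being catabolite-repressed by glucose. Full
derivations, assumptions and parameter rationale are in
`vignettes/mucodyn-methods.Rmd`.

## Worked example

```r
library(mucodyn)

params <- model_params()                  # calibrated defaults
sim <- simulate_culture(scenario_config("BT_mono"), params)
peak_density(sim, "bt", "planktonic")
#> $value
#> [1] 1169031
#> $time_h
#> [1] 15
endpoint_ph(sim)
#> [1] 5.012592
```

A BT monoculture in plain WC medium peaks at ~1.17×10⁶ viable cells/µl
around 15 h and acidifies the medium to pH ≈ 5.0 — after which the viable
count collapses because BT has no energy source left to withstand the acid
it produced.

The numbered scripts under `analysis/` run the full study workflow and
write their tables to `results/`:

```sh
Rscript analysis/01_simulate_scenarios.R   # six scenarios + summary table
Rscript analysis/02_flow_pipeline.R        # gating + species assignment accuracy
Rscript analysis/03_calibration_recovery.R # parameter recovery study
Rscript analysis/04_interaction_analysis.R # interaction strengths, regressions
```

`01` prints, among others:

```
 - BT WC monoculture peaks at 1.2e+06 cells/ul (t = 15 h), endpoint pH 5.01
 - RI WC monoculture peaks at 7.1e+05 cells/ul; pH 5.84 at 24 h, rising to 6.03 by 120 h (slow-mode acid consumption)
 - Mucin raises the BT co-culture peak 2.6-fold (1.6e+06 vs 5.9e+05) and lowers RI's (1.5e+05 vs 3.6e+05)
```

and `04` closes the loop on the model's two linearity assumptions:

```
                 relation   slope intercept r_squared
          pH ~ total SCFA -0.0450       6.7         1
 BT attached ~ planktonic  0.4925       0.0         1
```

(the attached/planktonic slope 0.493 is exactly f/(1−f) for the fixed
attached fraction f = 0.33).

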