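---
title: "Models and methods behind mucodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mucodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucodyn)
```

`mucodyn` studies how two abundant human gut bacteria — the mucin-degrading
primary fermenter *Bacteroides thetaiotaomicron* (BT) and the butyrate
producer *Roseburia intestinalis* (RI) — interact in batch culture, with and
without mucin beads that emulate the gut's mucosal microhabitat. This
vignette documents the scientific choices in the package: the kinetic model
and its assumptions, the flow-cytometry classification pipeline, the
calibration machinery, the synthetic-data generator that stands in for raw
measurements, and the numerical decisions that make it all reproducible.

## The kinetic model

The model is an eleven-state ODE system integrated by `simulate_culture()`.
Each species carries three pools (cells/µl): a *fast* viable state growing
on the lumped glucose+pyruvate pool G, a *slow* viable state (for BT,
foraging on mucin-derived sugars M; for RI, converting the acetate+lactate
pool A to butyrate Bu), and an inviable pool fed by death. Substrate pools
(mM) are G, M, A, Bu and a lumped "other acids" pool (succinate+formate,
produced by BT only). Lumping glucose with pyruvate, acetate with lactate
and the mucin monosaccharides into single pools keeps the system
identifiable from bulk measurements; it deliberately gives up on
per-monosaccharide effects and on resolving when lactate, specifically, is
consumed.

Mechanisms, each tied to an observation the model must reproduce:

* **Monod growth with acid self-inhibition.** Growth on every substrate is
  `mu * S/(K+S)` scaled by a Hill factor in pH,
  `phi(pH) = pH^n / (pH^n + pH_half^n)` with `n = 16`. The steep exponent
  makes `phi` a soft switch: ~0.96 at the fresh-medium pH 6.7, 0.5 at
  `pH_half`, <0.05 at pH 4.5. BT is the acid-sensitive species
  (`pH_half_bt = 5.5` > `pH_half_ri = 4.8`), which is what lets RI keep
  growing at a pH that stalls BT.
* **Algebraic pH.** pH is not a state: it is
  `max(4, 6.7 - c_pH * total acid)`, reflecting the tight linear
  relationship between pH and the summed fermentation acids in this medium.
  `c_pH = 0.045` pH/mM makes BT's ~37 mM of acids from 15 mM sugar land at
  pH 5.0 and RI's ~20 mM at pH 5.8. The floor at pH 4 only guards parameter
  exploration; calibrated trajectories never reach it.
* **Growth-state switching.** Fast cells switch to the slow state at rate
  `k_switch * sigma(theta_G - G)` where
  `sigma(x) = 1/(1 + exp(-x/eps))` is a smooth threshold (`eps = 0.08` mM).
  RI's switch additionally requires low mucin sugars
  (`* sigma(theta_M - M)`): its diauxic shift to lactate/acetate only
  happens when no sugar alternative remains. BT's switch is gated on low
  glucose only — BT's slow mode *is* mucin foraging, so demanding low M
  would lock it out of the very state that uses M. Switching is one-way;
  the batch never returns to glucose excess.
* **Death.** BT loses viability at rate
  `d_bt * (1 - phi(pH)) * (1 - energy)` with
  `energy = max(G/(K_G+G), M/(K_M+M))`: acid stress kills BT only when no
  energy source remains to defend intracellular pH, which is why mucin
  rescues BT at pH 5. RI dies at a small constant rate `d_ri`; a pH-gated
  term would be negligible in RI's tolerated range and could not produce
  its observed slow decline. Death moves cells viable → inviable, so totals
  are conserved and the inviable pools are monotone — matching the
  observation that acidity costs BT viable (not total) counts.
* **Mucin.** The mucin polymer is treated as inexhaustible; what matters is
  the free pool M of released sugars. A fixed fraction of each species'
  cells is attached (`f_att_bt = 0.33`, `f_att_ri = 0.25`, the measured
  mean attachment shares), and attached viable cells release M at rate
  `r_M` per cell. BT's release is multiplied by `KI_G_bt/(KI_G_bt+G)`: its
  mucin-utilisation machinery is catabolite-repressed while glucose lasts,
  whereas RI's hydrolysis is left constitutive. This asymmetry matters: it
  makes BT a net *consumer* of free mucin sugars in co-culture (relieving
  RI, whose growth on glucose M inhibits via `KI_M_ri/(KI_M_ri+M)`), while
  an unrepressed BT release term would invert that interaction sign and
  simultaneously overshoot the RI monoculture suppression.
* **Cross-inhibitions.** Glucose inhibits BT's growth on M
  (`KI_G_bt = 0.25` mM), and mucin sugars inhibit RI's growth on G
  (`KI_M_ri = 0.4` mM) — both directions are needed to reproduce the
  mucin-condition peak ordering (BT up ~2x, RI down ~2.5x in co-culture).

### Default parameters

The study's own parameter values live in a supplement that ships separately
from the text, so the package carries its own calibrated default set
(`model_params()`), chosen once against the printed observables — peak
viable densities, peak timing, pH minima/endpoints and attached-compartment
maxima across all six scenarios — and then frozen. Any external set can be
swapped in from YAML via `read_params()` without code changes. Two printed
values deserve a note: the RI mucin-monoculture planktonic maximum
(4.5×10⁵ cells/µl) and its attached maximum (1.1×10⁵) imply an attachment
share of ~0.20, slightly below the measured fixed fraction 0.25 the model
uses; with the fraction fixed, no parameterisation can centre both numbers,
so the defaults split the difference (planktonic ~-16%, attached ~+14%).

Initial conditions: 2×10³ cells/µl inoculum per species (1 ml of an
OD 0.1 preculture into 60 ml) and `G0 = 15` mM (WC medium's glucose plus
pyruvate). The sampling grid (`sampling_grid()`) is the experimental one:
every 4 h to 48 h, every 12 h to 120 h.

### Numerics

`deSolve::lsoda` with `rtol = 1e-8` and `atol = 1e-10`. The tight absolute
tolerance is deliberate: the acetate+lactate pool starts at zero and is
consumed toward zero, and a looser atol lets the integrator undershoot
below the -1e-9 non-negativity contract the package enforces after
integration. The right-hand side clamps tiny negative inputs to zero so
rate laws remain defined mid-step; smooth logistic thresholds (rather than
discontinuous switches) keep the system within lsoda's comfort zone.
Peaks are read from an hourly grid, so reported peak times are exact to 1 h.

## Flow-cytometry pipeline

The pipeline turns per-event channel intensities (FSC, SSC, SYBR-Green,
propidium-iodide) into absolute per-species viable densities.

1. **Normalisation** (`normalize_events()`): per-channel inverse hyperbolic
   sine, then standardisation to zero mean and unit variance. asinh is the
   standard cytometry variance-stabilising transform — logarithmic for
   bright events yet defined at zero; a plain arcsine variant exists for
   data already scaled to [0, 1] but is not the default.
2. **Embedding** (`embed_events()`): a 3-D neighbour-graph embedding built
   in the package — exact 25-nearest-neighbour graph (Euclidean), fuzzy
   edge weights from per-point kernel calibration, spectral initialisation
   from the normalised graph adjacency, then batch attraction/repulsion
   refinement under a min-dist 0.1 kernel. Determinism is a contract: one
   seed drives every stochastic step, neighbour search is single-threaded
   and exact, and the same input and seed reproduce coordinates
   bit-identically.
3. **Gating** (`gate_categories()`): blank-overlap flags first (below),
   then PI-positive → inviable (regardless of SG), SG-positive/PI-negative
   → live, double-negative → debris. Thresholds default to the
   minimum-density valley between the two largest modes of a heavily
   smoothed kernel density estimate (`adjust = 3`; lighter smoothing lets
   substructure within the negative cloud masquerade as the second mode).
   Unimodal channels are refused — explicit thresholds must then be given.
4. **Blank removal** (`remove_blank_overlap()`): each blank-run event
   claims a ball in embedding space whose radius is proportional to the
   local blank density (cubed inverse of the distance to the 50th blank
   neighbour, normalised to the median neighbourhood), with radius zero for
   blank events in clearly sparse regions (beyond 1.5× the median
   spacing). Density-proportional radii are what make carryover safe: a
   handful of genuine cells washed into a blank run register as sparse and
   claim nothing, while the dense background cloud claims its whole
   neighbourhood. `k_density = 50` sets the scale of "a handful" — blank
   runs with more than ~50 co-located carryover cells would need a larger
   value.
5. **Species assignment** (`classify_species()`): 5000 live events per
   monoculture replicate are drawn and embedded with label supervision
   (cross-label edge weights down-weighted to 0.1), co-culture live events
   are reprojected as similarity-weighted averages of their 10 nearest
   training events in channel space, and species labels come from a
   distance-weighted 50-nearest-neighbour vote under the Mahalanobis metric
   of the training embedding. Vote margins are returned per event; they are
   a confidence readout, not a calibrated probability.
6. **Counting** (`count_populations()`): density = events / acquired
   volume × dilution, with the study's acquisition settings (10 µl at
   dilution 1:10 or 1:200) as the worked defaults.

The manual 3-D inspection step of the original workflow is replaced by the
oracle-based accuracy checks in the test suite; there is no interactive
step anywhere.

## Calibration

`fit_params()` minimises a weighted least-squares loss over any subset of
parameters, log-scaled inside their (positive) box bounds: Latin-hypercube
multistart for the global stage, `nlminb` for local refinement. The loss
blocks are log10(density+1) for counts — densities span four orders of
magnitude, and the +1 keeps washed-out points finite — plus metabolite (mM)
and pH blocks; default weights 1 / 0.02 / 1 put the three blocks on
comparable scales (a 20 mM metabolite residual should not drown a 0.3-unit
pH miss). All scenarios are fitted jointly with one shared parameter set,
mirroring a design in which a single parameterisation must explain every
culture condition. Identifiability is demonstrated by recovery rather than
asserted: with four free parameters the fit returns the generating values
essentially exactly on noise-free data and within a few percent under 10%
count noise with three replicates (see `analysis/03_calibration_recovery.R`
and the calibration tests).

## Synthetic data

`generate_timeseries()` overlays the model truth with multiplicative
lognormal count noise (a fixed CV, mean-preserving), additive truncated
Gaussian metabolite noise and additive pH noise — the error structure of
replicate scatter in bulk fermentation data. `generate_flow_events()` draws
labeled events from multivariate lognormal channel distributions per
population (live BT, live RI, inviable, debris, blank), with the BT/RI
scatter separation parameterised in within-population SD units so test
difficulty is a dial. The default geometry (live cells SG-bright/PI-dim,
inviable PI-bright, debris and blank dim and well separated from each
other) is an order-of-magnitude choice, not a fit to instrument data —
without the original FCS files the realistic channel covariances are
unknown, and the defaults say so here rather than pretending otherwise.

What passing tests do show: the pipeline recovers generator truth to the
contracted accuracies at the stated separations, and the estimators are
consistent. What they cannot show: performance on real instrument data with
spectral spillover, debris continua, or the live/inviable ambiguity that
arises when cells are mid-way through losing membrane integrity — the
regime the study itself flags as hard. The 2-SD separation cases in
`analysis/02_flow_pipeline.R` are the closest synthetic analogue of that
regime.

## Problem sizes

The analysis scripts and tests use 2 000–5 000 events per cytometry run,
120-hour simulations on hourly grids, and two-scenario calibration with two
multistarts — sizes chosen so the whole workflow re-runs from scratch in
minutes on a laptop while every contracted accuracy still has comfortable
margin. The generators scale to larger runs by changing one argument.

## Known limitations

* The model does not reproduce the transient second RI peak seen in
  plain-medium co-culture around 38 h; the mechanism is genuinely open
  (candidate explanations — lactate flow reversal, toxin release,
  necrophagy — are not encoded, and none is favoured by the data at hand).
* Propionate is absent by design (the medium lacks vitamin B12), as are
  gas-phase, redox and spatial effects; beads are a well-mixed compartment
  with a fixed attachment fraction, not a spatial habitat.
* Lactate's occasional, variable consumption is not resolved within the
  lumped acetate+lactate pool.
* Event tables are exchanged as CSV; binary FCS container support is out
  of scope for this package.
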