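# mgfabm

A fuzzy agent-based model of mesenchymal stem cell (MSC) population
growth and osteogenic differentiation under magnesium-ion stimulation,
with an iterative sensitivity-screening + approximate-Bayesian-computation
calibration engine.

## Who this is for

Researchers modeling how Mg²⁺ released by biodegradable implants (or
added to culture medium) regulates MSC behavior, and anyone who needs a
compact, fully scriptable testbed for calibrating stochastic agent-based
culture models against the kind of measurements cell-culture studies
actually report (live counts, viability, DNA, ALP/OC markers, growth
factors).

## The model in brief

Cells occupy a 3D lattice (one cell per 15 µm patch, 8 layers, solid
walls). Each hour, every cell passes seven inputs — Mg²⁺ concentration,
alkalinity (ambient-vs-internal pH gap), BMP2, TGF-β1, local cell
density, maturity, DNA damage — through a Mamdani fuzzy controller
(piecewise-linear membership functions, min/max inference, weighted
fuzzy-mean defuzzification) that emits action intensities in [0, 1].
Stochastic events then fire per step:

- proliferation chance = Ω(clock) · αP · fP · γP0, with Ω a logistic
  cell-cycle bias centered on T_cyc = 24 h,
- mortality chance = (1 + αPM·δP) · αM · fM · γM0, with δP a transient
  mitotic-damage flag on one daughter per division,
- migration chance = fMi (one patch, random vacant neighbor),
- differentiation: maturity += αD · fD · rD0 per hour, early/late channel
  split at the maturity threshold Mt.

TGF-β1 and BMP2 are reaction–diffusion fields (cell production and
consumption, first-order degradation, conservative no-flux diffusion);
medium and pH reset every 2.5 days for protocols longer than 3 days.
Calibration ranks the 20 free parameters with a resolution-IV two-level
fractional-factorial screen + ANOVA, sends the top five to rejection ABC
(distance 1 − R², with R² = 1 − Σ|sim − obs| / Σ|obs| per observable),
accepts parameters whose posterior IQR shrinks below half the prior IQR
at their posterior medians, and iterates until nothing new is inferred.

See `vignettes/model-and-calibration.Rmd` for the full account.

## Worked example

Day-3 live cell counts across Mg²⁺ conditions (20 replicate seeds,
30 × 30 × 8 world, 180 seeded cells):

```r
library(mgfabm)
protocols <- lapply(c(0.8, 3, 6, 12, 60), function(m)
  sim_protocol(m, n_seed = 180, days = 3, measure_days = 3,
               world_dim = c(30, 30, 8)))
agg <- run_experiment(protocols, default_params(), seed = 2024,
                      replicates = 20)
subset(agg, observable == "live_count")
#>   condition day observable   mean       sd
#> 1       0.8   3 live_count 643.10 18.01140
#> 3       3.0   3 live_count 683.45 24.55815
#> 5       6.0   3 live_count 681.55 25.55999
#> 7      12.0   3 live_count 614.30 25.15447
#> 9      60.0   3 live_count 480.35 14.58288
```

The stimulatory band (3–6 mM) outgrows the 0.8 mM control, 12 mM falls
slightly below it, and 60 mM — toxic and strongly alkaline — trails far
behind with depressed viability (~77% vs ~87%): the nonlinear Mg²⁺ dose
response the model is built around.

A self-contained parameter-recovery experiment (generate data at a known
truth, then re-infer it):

```r
truth <- default_params(gP0 = 0.28, aP = 1.6, gM0 = 0.008)
syn <- generate_study(study_protocols("study3", world_dim = c(9, 9, 6),
                                      n_seed = 10)[2],
                      truth, noise = 0, seed = 101, min_viability = 50)
fit <- make_fit_fun(syn$protocols, syn$data)
priors <- default_priors(c("gP0", "aP", "gM0", "aD", "rD0", "r_r", "wc"))
priors[priors$name == "gP0", c("lo", "hi")] <- c(0.05, 0.35)
priors[priors$name == "aP",  c("lo", "hi")] <- c(0.5, 2.5)
priors[priors$name == "gM0", c("lo", "hi")] <- c(0.001, 0.02)
eff <- ffd_screen(priors, fit, data = syn$data, seed = 5, replicates = 2,
                  min_runs = 32)
head(eff[order(-eff$effect), 1:2], 3)
#>   name    effect
#> 1  gP0 1.0000000
#> 2   aP 0.4543759
#> 3  gM0 0.3263795
```

The base proliferation chance dominates a live-count dataset, as it
should.

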