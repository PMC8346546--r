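---
title: "A fuzzy agent-based model of MSC growth and osteogenic differentiation under Mg ions: model, assumptions, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and calibration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgfabm)
```

## The biological problem

Mesenchymal stem cells (MSCs) drive bone regeneration: they proliferate
rapidly and differentiate along the osteoblastic lineage, and both
processes respond to the local chemical microenvironment. Magnesium-based
biodegradable implants release Mg²⁺ ions as they corrode, and culture
studies consistently find a nonlinear dose response: Mg²⁺ around 3–6 mM
stimulates growth and early differentiation, concentrations above roughly
1.8 mM inhibit late differentiation and matrix mineralization, and
20–40 mM is toxic. High Mg²⁺ also alkalizes the medium, which stresses
cells independently. `mgfabm` implements a stochastic, on-lattice
agent-based model of an MSC monolayer culture under these influences,
together with the calibration machinery needed to fit its free parameters
to culture measurements.

## Model structure

### World

Cells live on a 3D lattice (default 30 × 30 × 8 patches of 15 µm; 8
z-layers accommodate the multilayering seen in differentiating cultures),
one cell per patch, solid walls, with `z = 0` the culture surface. Cells
are seeded uniformly at random on the surface layer. Neighborhoods are
26-connected (Moore), truncated at the walls; the local cell density seen
by a cell is the occupied fraction of its neighborhood.

### Cell decisions: a Mamdani fuzzy controller

Each hour, every cell feeds seven inputs to a fuzzy-logic controller:

| input | levels | key breakpoints (defaults) |
|---|---|---|
| Mg²⁺ (mM) | negligible, inhibitory, stimulatory, high, destructive | negligible below 0.8; stimulatory peak `cmlt` = 4.5 in the 2–10 band; high peak `cmmt` = 15; destructive peak `cmht` = 30 in the 20–40 toxic band |
| alkalinity (pH gap) | none, mild, severe | severe reached at `A_t` = 1.0 |
| BMP2 (ng/mL) | negligible, stimulatory, neutral, inhibitory | stimulus onset 0.008; stimulatory 10–20; neutral 50–200; inhibitory 500–2000 |
| TGF-β1 (ng/mL) | negligible, stimulatory, saturated | stimulatory onset 0.05, plateau 14.2–36.3 |
| density | low, medium, high | `cclt1/cclt2` = 0.02/0.08, `ccht1/ccht2` = 0.5/0.8 |
| maturity | early, late | threshold `Mt` = 0.5 |
| DNA damage | low, high | crisp 0/1 |

Membership functions are piecewise linear (triangles, trapezoids,
shoulders); the levels' breakpoints that are free model parameters
(`cmlt`, `cmmt`, `cmht`, `A_t`, the four density marks, `Mt`) move with
the parameter set, the rest encode the literature concentration bands
listed above. Inference is standard Mamdani min/max: rule activation is
the minimum over clause degrees, a clause over several admissible levels
takes their maximum, and "at least k of n" antecedent groups evaluate to
the k-th largest member degree (exactly the min/max value of the expanded
OR-of-ANDs). Activated output levels are aggregated per action by maximum
and defuzzified by the weighted fuzzy mean of fixed representative values
(0.25 / 0.5 / 0.75 / 1 for low / medium / high / very high). When no rule
fires for an action the output defaults to 0 (no action) — a conservative
null. Outputs are the five intensities `fP`, `fM`, `fMi`, and the early-
and late-differentiation rates, all in [0, 1].

The rule base is data, loadable from YAML (`read_controller()`); the
shipped default encodes: stimulatory Mg/BMP2/TGF-β1 upregulate
proliferation and early differentiation; everything above negligible Mg,
stimulatory TGF-β1 and severe alkalinity downregulate late
differentiation while stimulatory BMP2 upregulates it; destructive Mg,
severe alkalinity, inhibitory BMP2, crowding, solitude and DNA damage
raise mortality and depress proliferation (two or more simultaneous
severe insults raise mortality further); mild alkalinity affects growth
but not differentiation; high density triggers migration (contact
inhibition). A deliberately naive second implementation
(`fl_evaluate_naive()`) that expands every rule and evaluates it with
scalar loops serves as an internal oracle; the vectorized evaluator is
required to agree with it to machine precision.

### Events

Proliferation, mortality and migration are Bernoulli events per hourly
step:

- proliferation chance = Ω(clock) · αP · fP · γP0, with
  Ω(t) = 1 / (1 + exp(−k_Ω (t − T_cyc))) the logistic cycle bias
  (k_Ω = 0.5 h⁻¹, T_cyc = 24 h) concentrating divisions near the end of
  the cell cycle;
- mortality chance = (1 + αPM δP) · αM · fM · γM0, where δP marks one
  randomly chosen daughter of the most recent division (mitotic damage)
  and decays after one cell cycle;
- migration chance = fMi, a move of one patch to a uniformly random
  vacant neighbor.

Both chance products are unbounded, so they are clamped to [0, 1].
Differentiation is continuous: maturity grows by αD · fD · rD0 per hour
(early or late channel selected by `Mt`), capped at 1, and can co-occur
with division. Daughters are placed in a uniformly random vacant Moore
neighbor; a fully surrounded cell defers division (contact inhibition)
rather than aborting it. Within a step the order is mortality →
proliferation → migration → differentiation, with cells processed in
random order inside each event; cells born in a step act from the next
step on. DNA damage is crisp and absorbing: drawn once at seeding with
chance γC (passaging damage), and set deterministically by one hour of
exposure to ambient pH ≥ pH_t. Internal pH relaxes toward ambient at
r_r pH/h without overshoot; the controller's alkalinity input is the
remaining gap.

### Environment

Mg²⁺ and pH are spatially uniform (ions equilibrate much faster than
proteins in a culture well); ambient pH follows the affine map
pH = pH₀ + s·(Mg − Mg₀) (pH₀ 7.4 at the 0.8 mM control, s = 0.02 pH/mM,
clamped at 10), an empirical stand-in for the alkalization caused by high
Mg²⁺. TGF-β1 and BMP2 are per-patch fields with per-cell production
(higher in the early differentiation phase than late, reflecting the
greater secretory activity of less mature cells), first-order cellular
consumption weighted by `wc`, first-order degradation, and explicit
finite-difference diffusion with no-flux walls (sub-stepped to the 1/6
stability bound; the edge-replicated stencil is exactly conservative).
The default diffusivity (100 µm²/h) represents hindered transport in the
cell layer and is configurable. Every 2.5 days — only in protocols longer
than 3 days — a medium change resets the fields and pH exactly to their
initial values, cells untouched.

### Observables

Measurements mirror what culture studies report: live cell count;
viability = 100 · alive / (alive + cumulative dead); DNA content ∝ live
count; ALP (early marker) = Σ maturity/Mt over cells below `Mt`; OC (late
marker) = Σ (maturity − Mt)/(1 − Mt) over cells at or above it; growth
factors as medium totals. The κ scale factors are configurable and default
to 1; they are deliberately not part of the default 20-parameter free
pool.

## Calibration

The 20 free parameters (γP0, γM0, αP, αM, αPM, αD, rD0, Mt, γC, pH_t,
r_r, A_t, cmlt, cmmt, cmht, the four density marks, wc) get uniform
priors over plausible ranges. Calibration iterates:

1. **Screen.** A two-level resolution-IV fractional factorial over the
   current free pool (a fold-over of an interaction-column assignment in a
   2^b base factorial, so main effects are orthogonal and clear of
   two-factor interactions), scored by the fit metric; main-effect F
   statistics (exact closed form for the orthogonal ±1 design) are scaled
   to max 1 and rank the parameters.
2. **Select** the top five.
3. **ABC.** Rejection sampling: draw parameter vectors from the selected
   priors (others fixed at accepted medians or defaults), simulate, keep
   the best by the distance 1 − R², where
   R² = 1 − Σ|sim − obs| / Σ|obs| per observable, averaged over
   observables (1 is a perfect fit, 0 a simulation stuck at zero).
4. **Narrow.** A parameter is accepted at its posterior median when the
   posterior IQR is strictly below ρ = 0.5 times the prior IQR; otherwise
   it returns to the free pool.
5. Repeat until an iteration accepts nothing new (optionally also when
   the improvement of the mean top fit drops below a tolerance, a stricter
   stopping rule exposed as `min_delta_r2`).

Datasets lacking viability measurements can declare a minimum-viability
constraint (conventionally 50%): parameter sets whose simulated viability
drops below it anywhere get the worst distance in ABC, and the screen
assigns them the worst valid score. Without this, the screen's ranking is
corrupted by a pathology of count-only fitting — extreme mortality
"fixes" overshooting populations by erasing them — and mortality
parameters mask the proliferation parameters that actually drive the
counts.

### Design notes and numerical choices

- **t-norm/s-norm**: min/max (the Mamdani default), chosen for exact
  reproducibility and because the "k of n" groups then reduce to order
  statistics.
- **Defuzzification** uses fixed representative output values rather than
  centroids of output membership functions; with evenly spaced
  representatives the two coincide up to scaling, and representatives
  keep the output exactly interpretable.
- **Screen replicates**: the fit of a single stochastic run is noisy (two
  runs differing only in a 10⁻⁴ perturbation diverge like independent
  seeds after a few hundred steps), so the screen supports replicate
  averaging and enlarged designs; the shipped recovery experiment uses 2
  replicates on a 32-run design, which in piloting lifted real effects to
  F ≈ 10–25 while null parameters stayed at F ≲ 4.
- **Common random numbers**: all design rows share simulator seeds, so
  row contrasts reflect parameters, not seed luck.
- **Probability clamping** to [0, 1] handles the unbounded chance
  products.
- **Tie-breaks**: top-k selection breaks effect ties by parameter name;
  degenerate posteriors (all runs violating constraints) are flagged and
  never accepted.

## The synthetic-study generator

`generate_study()` runs the simulator at a known ground-truth parameter
set over one of three protocol templates shaped like typical calibration
studies — (1) five Mg conditions (0.8/3/6/12/60 mM) with live count and
viability at day 3; (2) two conditions (0.78/5 mM) with ALP, OC, DNA and
medium growth factors at days 7/14/21; (3) four conditions (0.8/3/6/14
mM) with live counts at days 3/6/9 — and applies Gaussian relative
observation noise (default 15%, the typical magnitude of culture error
bars). The day-3 schedule for template 1 is this package's choice; the
source studies report no schedule for it, only that it was the shortest.
What the generator emulates is the *shape* and stochasticity of such
data, not any particular laboratory's numbers: passing recovery tests
shows the calibration machinery can invert the simulator, not that the
model is a validated description of any real culture.

## Scaled-down study sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the relevant effects are comfortably resolved:
the Mg-ranking experiment uses the full 30 × 30 × 8 world with 180 seeded
cells and 20 replicate seeds at day 3; the parameter-recovery experiment
uses a 9 × 9 × 6 world with 10 seeded cells, one 3 mM condition of the
study-3 template, a 7-parameter pool, a 32-run screen with 2 replicates,
and ABC with 500 runs keeping the top 20 over at most 2 iterations. The
recovery ground truth (γP0 = 0.28, αP = 1.6, γM0 = 0.008) sits toward the
upper part of the γP0 prior on purpose: a two-level screen estimates
*main* effects, and a truth at the center of the prior box makes the fit
response non-monotone in the proliferation parameters (undershoot on one
side, overshoot on the other), pushing their signal into interactions
that a resolution-IV screen deliberately ignores. αP·γP0 (and likewise
αM·γM0) enter the event chances only as products, so only the product is
identifiable; the recovery pool therefore holds αM fixed, and the truth
lies near the log-center of the identifiable ridge, where posterior
medians of both factors are meaningful.

## Known limitations

- The rule base aggregates inputs by superposition; synergies (e.g.
  Mg²⁺ × growth factors) are not modeled.
- Only the osteoblastic lineage is represented; no spreading, adhesion
  mechanics, or substrate stiffness.
- The pH–Mg map is affine and instantaneous; real alkalization kinetics
  (buffering, CO₂ exchange) are richer.
- The growth-factor production law is a two-rate (early/late) constant
  model; real secretion varies continuously with differentiation state.
- Observable mappings for ALP/OC are linear in maturity weights; real
  marker expression is nonlinear and time-lagged.
- On-lattice movement quantizes positions to 15 µm patches; it was chosen
  (over off-lattice) for the performance the calibration loop requires.

## A minimal session

```{r example, eval = FALSE}
params <- default_params()
ctrl <- default_controller(params)
fl_evaluate(ctrl, data.frame(maturity = 0.1, dna_damage = 0, mg = 4.5,
                             alkalinity = 0, bmp2 = 0, tgfb1 = 0,
                             density = 0.2))

protocols <- lapply(c(0.8, 3, 6), function(m)
  sim_protocol(m, 180, 3, 3, world_dim = c(30, 30, 8)))
run_experiment(protocols, params, seed = 1, replicates = 5)

syn <- generate_study("study3", default_params(gP0 = 0.25), noise = 0,
                      seed = 1, world_dim = c(10, 10, 6), n_seed = 12,
                      min_viability = 50)
fit <- make_fit_fun(syn$protocols, syn$data)
calibrate(default_priors(c("gP0", "aP", "gM0")), fit, syn$data,
          k_top = 3, n_runs = 200, n_keep = 20, max_iter = 2, seed = 1)
```
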