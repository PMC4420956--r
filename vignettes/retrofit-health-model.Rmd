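---
title: "Modelling the health effects of home energy-efficiency retrofits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health effects of home energy-efficiency retrofits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeqaly)
```

# The question

Energy-efficiency retrofits (insulation, glazing, draught proofing, better
boilers) make homes warmer and cheaper to heat, but they also make them more
airtight. A tighter envelope concentrates pollutants generated indoors —
fine particles from cooking, secondhand tobacco smoke, radon, moisture that
feeds mould — while reducing the ingress of outdoor particles. Whether a
national retrofit programme improves or harms health therefore depends
critically on whether purpose-provided ventilation (trickle vents, extract
fans) is installed alongside the fabric work.

`homeqaly` models this trade-off end to end for a synthetic national
dwelling stock. It compares three ventilation policies applied with the same
fabric retrofits:

* **`regulation`** — trickle vents and extract fans installed wherever they
  are absent (ventilation standards always enforced);
* **`installer_discretion`** — ventilation added only in homes with a
  perceptible problem (baseline mould risk above a threshold);
* **`no_added_ventilation`** — fabric measures only.

Broken extract fans are repaired, and trickle vents accompany replacement
glazing, in all three. Results are quality-adjusted life years (QALYs)
gained or lost per 10,000 persons over a 50-year follow-up.

# Model structure

The pipeline is a chain of data-frame-first functions:

```
generate_stock() -> generate_population() -> generate_mortality()
        |                                          |
assign_measures() -> apply_measures()              |
        |                                          |
compute_exposures() -> person_deltas() -> run_life_table() / morbidity
        |                                          |
        +---------------- run_hia() ---------------+
```

## 1. Synthetic stock, occupants and mortality

`generate_stock()` draws dwellings whose continuous fields (floor area,
fabric heat loss, envelope permeability, heating efficiency, outdoor PM2.5,
radon source strength, moisture load) are independent truncated normals.
The configured mean/SD pairs are treated as moments of the *observed*
(truncated) distributions, so the parent parameters are solved by moment
matching — naive truncation at zero would bias the fabric heat-loss mean
upwards by about 15 W/K. Categorical fields (dwelling type, smoker
household, ventilation devices, retrofit-eligibility flags) are Bernoulli
draws at configured prevalences. Everything is a pure function of
`(n, params, seed)`.

`generate_population()` places a household in every dwelling (mean 2.36
persons), with ages drawn from the stationary pyramid implied by the
mortality schedule. `generate_mortality()` builds sex-specific
Gompertz–Makeham all-cause schedules for ages 0–100 with smooth
age-dependent cause fractions (myocardial infarction, stroke, the wider
cardiopulmonary group, lung cancer), plus a configurable share of
cardiovascular deaths flagged as seasonal winter excess — the only
mortality component modified by indoor temperature.

The generator is calibrated, not survey-driven: with default parameters a
stock of a few thousand dwellings reproduces the baseline stock means the
model targets (fabric heat loss 294 W/K, permeability 16 m³/m²/h, SIT
17.8 °C, indoor-source PM2.5 9.4 µg/m³, outdoor-origin indoor PM2.5
6.2 µg/m³, radon 22.9 Bq/m³, 14.9% of homes with mould, heating energy
22.9 MWh/y). It does **not** emulate joint correlations between dwelling
characteristics, regional variation, or tenure.

## 2. Building physics (exposure engine)

A deliberately transparent single-zone surrogate:

* infiltration air-change rate from permeability by the engineering "rule
  of 20", plus fixed contributions from trickle vents and working extract
  fans, floored at 0.3/h for occupant window opening;
* steady-state well-mixed mass balance for indoor-source PM2.5 (continuous
  cooking-equivalent source, 65% source capture by a working extract fan,
  first-order deposition, room-occupancy weighting), outdoor-origin PM2.5
  (penetration × ach dilution), and radon (source strength / ach);
* standardised internal temperature (SIT) as a linear function of total
  (fabric + ventilation) heat loss, two-point calibrated so 369 W/K gives
  17.8 °C and an 80 W/K reduction gives +0.3 °C;
* secondhand-smoke index proportional to 1/ach in smoker households,
  normalised so the baseline smoker-household mean is 1;
* mould risk as a logistic function of moisture load per air change and
  SIT;
* annual heating energy from total heat loss, degree-hours and system
  efficiency.

The physics constants marked "calibrated" in `hia_params()` were fitted
once, on a 400,000-dwelling generated stock, so that baseline stock-mean
exposures reproduce the targets above; they are configuration, not
measurements. Exposure changes are applied instantaneously at year 0.

## 3. Health engine

Five mortality pathways act through sex- and age-resolved annual life
tables: SIT on winter-excess cardiovascular deaths (RR 0.98/°C), the smoke
index on stroke (1.25) and myocardial infarction (1.30), PM2.5 on
cardiopulmonary (1.082 per 10 µg/m³) and lung cancer (1.059 per 10 µg/m³),
and radon on lung cancer (1.16 per 100 Bq/m³). Risks scale log-linearly
(`rr^(delta/unit)`) and combine multiplicatively per person; the mean
within each (sex, age) cell is the cohort hazard multiplier.

The life-table engine works in rate space: annual death probability
`q = 1 − exp(−R)`, deaths at mid-year, every cohort alive at year 0
projected 50 years with the schedule held constant. Cause-specific rates
are a disjoint partition summing exactly to the all-cause rate (the
cardiopulmonary remainder excludes MI and stroke; the winter overlay is
carved proportionally from the cardiovascular components). Each pathway's
effect phases in through a lag function: immediate for temperature,
`1 − exp(−t/2.5)` for cardiovascular effects of smoke and particles, and a
5-year latency then linear ramp to year 20 for lung cancer. Each mortality
outcome is evaluated on its own life-table run and the net impact is the
sum — pathway attribution, not a single combined table.

Morbidity enters three ways: years lived with disability avoided,
proportional to the mortality life-years via cause-specific YLD:YLL
ratios; common mental disorders in adults (RR 0.90 per °C of SIT, benefit
decaying exponentially and truncated at 10 years); and childhood asthma
events scaling with mould prevalence (harm-class RRs 1.53/1.53/1.83 per
100 percentage points). Utility weights, YLD:YLL ratios and baseline
prevalences are declared placeholder configuration.

## 4. Uncertainty and structural sensitivity

`run_monte_carlo()` (default 500 iterations; examples below use fewer)
draws, independently per iteration: lognormal relative risks (median at
the point estimate), normal scale factors on the retrofit fabric /
permeability / ventilation deltas, and beta utility weights. Each
iteration derives its own RNG substream from `(seed, iteration)` alone, so
results are independent of evaluation order. Intervals are empirical
2.5th/97.5th centiles. A dispersion of zero makes a parameter exactly
degenerate, so an all-degenerate run reproduces the deterministic analysis
bit for bit.

Two structural analyses probe the model's weakest assumptions:

* `sensitivity_high_risk()` concentrates all winter-excess cardiovascular
  mortality in a fraction *p* of the population (1, 0.1, 0.01, 0.001). The
  stratum hazard is solved numerically so the stratified table reproduces
  the base-year expected cardiovascular deaths — the quantity pinned down
  by observed (cross-sectional) mortality data — to 1e-8 relative.
  Full-horizon death conservation is infeasible for very small *p* (the
  stratum cannot supply 50 years of winter deaths), which is why the
  year-0 quantity is the conserved one. As *p* shrinks, those saved from
  cold have ever-shorter remaining life expectancy and the benefit
  vanishes; *p* = 1 returns the unstratified analysis exactly.
* `sensitivity_pm_toxicity()` multiplies the indoor-source component of
  the PM2.5 change by `theta` in [0, 1]; `theta = 1` is bit-identical to
  the base run, `theta = 0` removes the indoor-source effect entirely and
  can flip the sign of the cardiopulmonary impact in tightening-dominated
  scenarios.

# A worked example

Problem sizes here are chosen for a quick vignette build; the package's
acceptance runs use 5,000 dwellings and 200 Monte Carlo iterations.

```{r example}
params <- hia_params()
stock <- generate_stock(1000, params, seed = 1)
occupants <- generate_population(stock, params, seed = 2)
schedule <- generate_mortality(params)

res <- run_hia(stock, occupants, schedule, "regulation", params)
res
```

```{r tidy}
tidy(res)     # one row per outcome
glance(res)   # one-row run summary
```

```{r scenarios}
nets <- sapply(c("regulation", "installer_discretion",
                 "no_added_ventilation"), function(sc) {
  run_hia(stock, occupants, schedule, sc, params)$net_qaly_per_10k
})
round(nets, 1)
```

```{r mc, fig.width = 6, fig.height = 3.5}
settings <- mc_settings(n_iterations = 50, seed = 1)
mc <- run_monte_carlo(
  hia_mc_pipeline(stock, occupants, schedule, "regulation", params),
  settings)
autoplot(mc)
```

Every default is overridable through nested lists or a YAML file:

```{r config, eval = FALSE}
p2 <- hia_params(health = list(horizon = 20),
                 physics = list(pm_deposition = 0.3))
p3 <- read_hia_config("my_config.yaml")   # merged over the defaults
```

# Numerical choices

* Forces of mortality, not probabilities, are the primitive everywhere;
  conversion `q = 1 − exp(−R)` happens once, in the projection.
* The cause partition is exact: the six disjoint rates sum to the
  all-cause rate to 1e-12, so a null intervention gives exactly zero.
* Constant-hazard life expectancy closes to `(1 − q/2)/q`, the mid-year
  discrete analogue of `1/h`, which the test suite checks to 1e-12.
* Truncated-normal fields use moment matching (solved via
  `truncnorm::etruncnorm`/`vtruncnorm`) so configured means/SDs are the
  truncated moments.
* The stratum-hazard solve uses `uniroot` on the log scale to 1e-13.

# Limitations

* The synthetic stock has independent marginals; real stocks correlate
  age, fabric, tenure and occupancy, which matters for targeting analyses.
* The single-zone physics surrogate has no inter-zonal flows, weather
  dynamics, or occupant behaviour beyond a fixed window-opening floor.
* Exposure-response relationships are log-linear with multiplicative
  combination and no thresholds.
* Utility weights, YLD:YLL ratios, CMD/asthma baselines and the winter
  excess share are placeholder configuration, so morbidity magnitudes are
  indicative; orderings and signs are the robust outputs.
* The mortality schedule is held constant over the 50-year horizon (no
  secular improvement), and the intervention is instantaneous at year 0.
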