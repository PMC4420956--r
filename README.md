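# homeqaly

Health impact modelling of home energy-efficiency retrofits.

## The scientific problem

Energy-efficiency retrofits (insulation, glazing, draught proofing, better
heating) make homes warmer and cheaper to heat — but also more airtight.
Tightening the envelope concentrates indoor-generated pollutants (cooking
PM2.5, secondhand tobacco smoke, radon, the moisture that feeds mould)
while reducing the ingress of outdoor particles. The net health effect of
a national retrofit programme therefore hinges on whether purpose-provided
ventilation (trickle vents, extract fans) accompanies the fabric work.

`homeqaly` models this trade-off end to end on a seeded synthetic national
dwelling stock. It compares three ventilation policies applied with the
same fabric retrofits:

| scenario | ventilation policy |
|---|---|
| `regulation` | trickle vents and extract fans installed wherever absent |
| `installer_discretion` | added only in homes with a perceptible mould problem |
| `no_added_ventilation` | fabric measures only |

and reports quality-adjusted life years (QALYs) per 10,000 persons over a
50-year follow-up, by outcome.

## The model

- **Synthetic data** — `generate_stock()` draws dwellings from
  moment-matched truncated normals plus Bernoulli flags;
  `generate_population()` links households (mean 2.36 persons) with ages
  from the stationary pyramid; `generate_mortality()` builds sex-specific
  Gompertz–Makeham schedules with smooth cause-fraction curves and a
  winter-excess cardiovascular overlay. Everything is a pure function of
  `(params, seed)`.
- **Exposure engine** — a single-zone steady-state mass balance: the
  "rule of 20" converts envelope permeability to infiltration; trickle
  vents and working extract fans add fixed air-change contributions;
  indoor-source and outdoor-origin PM2.5, radon, a secondhand-smoke index,
  mould risk, standardised internal temperature (SIT) and heating energy
  all follow from the air-change rate and heat loss.
- **Health engine** — five mortality pathways (SIT → winter cardiovascular,
  smoke → stroke/MI, PM2.5 → cardiopulmonary/lung cancer, radon → lung
  cancer) run through annual sex/age life tables in rate space with
  disease-specific lag functions; morbidity adds YLD:YLL ratios, a common
  mental disorder prevalence model and childhood asthma events.
- **Uncertainty** — `run_monte_carlo()` draws lognormal relative risks,
  normal retrofit-delta scale factors and beta utility weights with
  per-iteration substreams; `sensitivity_high_risk()` and
  `sensitivity_pm_toxicity()` are structural sensitivity analyses for the
  two weakest assumptions.

See the vignette (`vignettes/retrofit-health-model.Rmd`) for the full
model description, calibration notes and limitations.

## Worked example

```r
library(homeqaly)

params    <- hia_params()
stock     <- generate_stock(1000, params, seed = 1)
occupants <- generate_population(stock, params, seed = 2)
schedule  <- generate_mortality(params)

res <- run_hia(stock, occupants, schedule, "regulation", params)
res
#> Health impact over 50 years -- regulation scenario
#>   1000 dwellings, 2391 persons
#>          outcome qaly_mortality qaly_morbidity qaly_per_10k
#>        winter_cv           12.7            0.6         13.3
#>               mi           -3.8           -0.7         -4.5
#>           stroke           -2.1           -0.9         -3.0
#>  cardiopulmonary          194.0          106.7        300.7
#>      lung_cancer           46.1            9.2         55.3
#>              cmd            0.0            9.5          9.5
#>           asthma            0.0            0.3          0.3
#>   Net impact: 371.7 QALYs per 10 000 persons
```

`tidy(res)` returns the per-outcome tibble, `glance(res)` a one-row
summary, and `autoplot(res)` a per-outcome bar chart. Comparing the three
policies on the same stock:

```r
sapply(c("regulation", "installer_discretion", "no_added_ventilation"),
       function(sc) run_hia(stock, occupants, schedule, sc, params)$net_qaly_per_10k)
#>           regulation installer_discretion no_added_ventilation
#>                371.7               -305.5               -359.9
```

Retrofitting with enforced ventilation yields a net health benefit;
retrofitting without it causes net harm — the indoor-pollutant burden
outweighs the warmth benefit. Monte Carlo intervals:

```r
mc <- run_monte_carlo(
  hia_mc_pipeline(stock, occupants, schedule, "regulation", params),
  mc_settings(n_iterations = 500, seed = 1))
tidy(mc)       # point + 2.5/97.5 centile per outcome
autoplot(mc)   # pointrange plot
```

Every default — stock moments, physics constants, exposure–response
table, lags, utility weights, Monte Carlo settings — is overridable via
nested lists (`hia_params(health = list(horizon = 20))`) or a YAML file
(`read_hia_config()`). `cmd_generate()` / `cmd_run()` and the
`inst/scripts/homeqaly` wrapper drive the same pipeline from files and the
shell.

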