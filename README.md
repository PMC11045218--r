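# divherb

Hierarchical Bayesian analysis of multi-site plant-diversity experiments:
herbivory, insect damage richness, and plant survival under manipulated
intraspecific richness, interspecific richness and water availability.

## What this package is for

Biodiversity–ecosystem-function ("BEF") field experiments plant plots of a
focal genus (here, *Piper*) under crossed treatments — genetic diversity
within a species (low/high, `A`), number of species per plot standardized by
the site pool (`S`), and water addition at a subset of sites (`W`) — and
record, per leaf, the percent area consumed by each insect damage taxon.
`divherb` implements the full analysis chain for such experiments:

- **Hierarchical Bayesian models** (`hbm()`) with site-level coefficient
  hierarchies, the Bayesian analogue of a random-effects model with site as
  the random factor:

  y_i = α_s(i) + Σ_X β^X_s(i)·X_i + ε_i, ε_i ~ N(0, σ²_s(i)),
  α_s ~ N(μ_α, τ_α²), β^X_s ~ N(μ_X, τ_X²)

  with weakly informative priors (Normal(0, 100) locations, half-Cauchy(5)
  scales), fitted by a blocked adaptive random-walk Metropolis sampler
  (`run_chains()`) written for this package.
- **Bayesian structural equation models** (`bsem()`): per-site two-equation
  path models linking treatments, insect damage richness `R` and herbivory
  `H` (paths A–G), with standardized path coefficients, indirect effects,
  and DIC-based selection among the candidate water-path structures
  (variants I, II, III, no-water) via `compare_bsem()`.
- **Diagnostics**: split-chain Gelman–Rubin R-hat (`gelman_rubin()`, 1.1
  threshold), probability of direction (`p_direction()`), equal-tailed
  credible intervals, posterior predictive checks with a sum-of-squares
  discrepancy (`ppc()`; ≈ 0.5 means well calibrated), and DIC (`dic()`).
- **Survival analysis**: Kaplan–Meier curves (`km_curves()`) and Cox
  proportional-hazards fits (`fit_cox()`, Efron ties) for plant mortality,
  including the intraspecific × water interaction.
- **A synthetic-experiment generator** (`piper_sites()`, `piper_truth()`,
  `simulate_experiment()`) that emulates the five-site study design with
  known ground truth, so every stage is verifiable by parameter recovery.
- **A pipeline** (`run_full_analysis()`) that runs
  simulate/ingest → derive → fit → diagnose → report from a YAML config and
  writes CSV/JSON outputs with full run metadata.

## Worked example

```r
library(divherb)

# a full five-site synthetic experiment (water treatment at three sites)
dat <- simulate_experiment(piper_sites(), piper_truth(), seed = 42)
dat
#> Piper experiment data: 96 plots, 1152 plants, 3999 leaves, 5 site(s)
#>   17 validation flags

site_summary(dat)
#>        site mean_herbivory mortality_pct n_damage_taxa specialist_share
#> 1 CostaRica           25.6          80.2            10             64.5
#> 2   Ecuador           19.5          43.8            10             58.4
#> 3      Mogi           23.3          39.6             9             21.8
#> 4      Peru           19.0          24.7            10             28.2
#> 5    Uaimii           27.7          14.6             8             11.9

# cross-site model of leaf herbivory under water, intraspecific and
# interspecific richness (water sites only)
fit <- hbm(dat, "leaf_herbivory", covariates = c("W", "A", "S"),
           n_iter = 4000, n_burn = 800, seed = 1)
summarize_effect(fit, "mu_W")
#> Effect: -3.11 +/- 3.44 pp (95% CI -6.55 to 0.23), PD = 97.2%
```

The cross-site water effect `mu_W` is the expected change in percent leaf
area consumed when a plot is watered: here about −3 percentage points with
97% probability the effect is negative (the generator truth is −4.2, inside
the interval). `summary(fit)` lists every site-level and hyper-parameter
with median, mean, 95% CI, PD and R-hat.

```r
sf <- survival_frame(dat)
fit_cox(sf[sf$site == "CostaRica", ], c("W", "A", "S_planted"))
#> Cox proportional hazards fit (efron ties), 288 subjects, 231 events
#>       term    beta     se     z        p
#>          W -0.5290 0.1334 -3.97 7.33e-05
#>          A -0.1952 0.1320 -1.48 1.39e-01
#>  S_planted  0.0907 0.1582  0.57 5.66e-01
```

Watering reduces the mortality hazard (log-hazard −0.53, i.e. a hazard
ratio of 0.59; generator truth −0.45). Path models work the same way:
`bsem(dat, "CostaRica", variant = "III")`, then
`standardized_coefficients()`, `indirect_effect(fit, c("A", "E"))` and
`compare_bsem()` for DIC-based structure selection.

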