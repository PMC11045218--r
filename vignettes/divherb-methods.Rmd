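---
title: "Models and methods in divherb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in divherb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divherb)
```

## The scientific setting

`divherb` analyses multi-site biodiversity–ecosystem-function field
experiments in which plots of *Piper* plants are planted under crossed
treatments — intraspecific richness (clones of one mother plant vs cuttings
from distinct mothers), interspecific richness (one species up to the site's
species pool), and, at a subset of sites, water addition — and the responses
recorded are leaf-level insect herbivory (percent leaf area removed, summed
over damage taxa), the richness of insect damage types per leaf, plant-level
damage summaries, and plant survival. The package provides the full analysis
chain for such data: response derivation, hierarchical Bayesian models
(HBMs), Bayesian structural equation models (BSEMs), survival analysis, and
a synthetic-experiment generator with known ground truth so that every stage
can be verified by parameter recovery without access to field data.

## Response derivation

From the long-format leaf table (one row per taxon per leaf), total
herbivory per leaf is the sum of taxon damages, capped at 100 because
multiple taxa can consume overlapping leaf area; the data do not say whether
summed damage can exceed the leaf, so the cap is a package convention.
Damage richness is the count of taxa with strictly positive damage. At the
plant level the package derives the percentage of leaves with any damage and
the within-plant sample variance (n − 1 denominator) of leaf herbivory;
plants with a single leaf are flagged and excluded from variance analyses.
Because plants die during these experiments, the interspecific richness
covariate is the *realized* richness — distinct species among surviving
plants — standardized by the site pool size to lie in [0, 1], which makes
one unit of the covariate mean "from empty to full pool" at every site.
Plots whose plants all died are excluded from herbivory models (they carry
no leaves) but retained in survival analysis. Survival models instead use
the *planted* richness, since mortality is early and is itself the process
under study.

## The hierarchical model

For response $y_i$ at observation (leaf or plant) $i$ in site $s(i)$:

$$y_i = \alpha_{s(i)} + \sum_X \beta^X_{s(i)} X_i + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathrm{N}(0, \sigma^2_{s(i)})$$

with $X$ ranging over water addition $W \in \{0,1\}$, high intraspecific
richness $A \in \{0,1\}$, standardized interspecific richness $S \in [0,1]$,
and, for the herbivory response only, the leaf's damage richness $R$ (the
per-taxon effect on herbivory). Under the cross-site scope the site
coefficients are exchangeable draws from cross-site hyperdistributions,
$\alpha_s \sim \mathrm{N}(\mu_\alpha, \tau_\alpha^2)$ and
$\beta^X_s \sim \mathrm{N}(\mu_X, \tau_X^2)$ — the Bayesian analogue of a
random-effects model with site as the random factor, which accommodates the
fact that treatment levels differ between sites. Water-effect models use
only the sites that carried the water treatment; richness models use all
sites. Optional $W\times A$ and $W\times S$ interaction terms quantify
whether diversity modulates the water response; the $W\times A$ interaction
is refused at sites where mortality emptied one of the four treatment cells,
because the contrast is not estimable there. A normal likelihood is used for
all four responses, including the bounded and count-valued ones — the
package's posterior predictive check is the instrument for judging whether
that simplification is adequate on a given data set.

Priors are weakly informative on a 0–100 response scale: Normal(0, sd 100)
on all location parameters and half-Cauchy(scale 5) on all standard
deviations ($\sigma_s$, $\tau$). Single-site fits use the location prior
directly on the coefficients. These are conventional weak choices; on count
responses (damage richness, typically 0–10) they are effectively flat.

Treatment effects are reported in the field's "$x \pm y$" form: posterior
median, the 95% equal-tailed credible interval expressed as a half-width,
and the probability of direction (PD) — the share of the posterior on the
median's side of zero, in [50, 100]. Herbivory effects are reported in
percentage points (the response is already a percentage); for count-like
responses `summarize_effect(..., scale = "percent_relative")` divides by a
baseline, defaulting to the observed mean response in the reference
condition (covariate at its minimum). The denominator of relative effects is
genuinely ambiguous in published practice; the default is stated here and in
the function documentation precisely because it is a choice.

## The path models

Per site, at the leaf level, two linked regressions encode the causal
structure among treatments, damage richness $R$ and herbivory $H$:

$$R_i = \alpha_R + a_A S_i + a_C A_i \,(+\, a_G W_i) + \varepsilon_{R,i}$$
$$H_i = \alpha_H + a_B S_i + a_D A_i \,(+\, a_F W_i) + a_E R_i +
  \varepsilon_{H,i}$$

Paths are labelled A–G: diversity→richness (A, C), diversity→herbivory
(B, D), richness→herbivory (E), water→herbivory (F), water→richness (G).
The four candidate structures differ only in the water paths: variant I has
both F and G, variant II only G, variant III only F, and `no_water` neither
(the structure for sites without the treatment). Errors are independent
normals; residual correlation between the two equations and plot-level terms
are deliberately out of scope. Standardization is post hoc — each raw
coefficient draw is multiplied by sd(predictor)/sd(outcome) computed from
the site data, binary treatments included — so raw and standardized
summaries come from a single fit and standardized coefficients are invariant
to affine rescaling of any variable. Indirect effects are per-draw products
of standardized coefficients along a path chain (e.g. $a_A a_E$ for
S→R→H).

Variants are compared by DIC, $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$. Fits within 2 DIC units of the best are
treated as ties and resolved toward the variant with fewer active paths;
"2 units" is the conventional indifference zone, chosen here because the
selection rule needs a numeric boundary.

## Sampling and diagnostics

All posteriors are simulated by a blocked adaptive random-walk Metropolis
sampler (`run_chains()`) that needs only log-density evaluations: one block
per site plus separate blocks for the location and scale hyperparameters
(the scales sit in a funnel-shaped conditional and mix better on their own);
one block per equation for the BSEMs. Proposal scales adapt only during
burn-in, targeting roughly 20–50% acceptance, and are frozen afterwards so
the retained chain is a valid time-homogeneous Markov chain. Block proposals
are seeded with least-squares standard errors, which makes short runs
usable. Three chains with over-dispersed, data-informed starting values are
the default; chains use independent substreams derived from the single seed,
and the same seed reproduces every draw exactly. Defaults are 10,000
iterations with 1,000 burn-in, and 20,000/5,000 for interaction models,
which are harder to mix. An external sampler can be swapped in by supplying
any function that maps a parameter vector to a log posterior.

Convergence is judged by the split-chain Gelman–Rubin statistic with the
conventional 1.1 threshold; the pipeline refits a failing model once at
doubled iterations before giving up. Model fit is judged by a posterior
predictive check with the residual sum of squares as discrepancy: for each
retained draw, replicate data are simulated from the normal likelihood and
$T = \sum_i (y_i - \hat y_i(\theta))^2$ is compared between replicate and
observed data. Exact ties count one half, so a degenerate perfectly
replicating model scores exactly 0.5; values near 0 or 1 indicate misfit
(in particular, a model whose variance is 10× too small scores near 0).
Credible intervals are equal-tailed percentile intervals, not
highest-density regions, matching the reporting convention the summaries
mirror. The PD of an exactly sign-balanced posterior is 50 by the
zero-splitting convention.

## Survival analysis

Survivorship is summarised by Kaplan–Meier product-limit curves and analysed
with Cox proportional-hazards models (Efron tie handling by default,
Breslow by flag), via the `survival` package behind the package's own
surface. Species identity enters reference-coded; the intraspecific ×
water interaction is supported. The descriptive "percent survival
difference" between two arms is defined as the relative difference of the
end-of-study Kaplan–Meier values, $100\,(S_T(T)-S_R(T))/S_R(T)$ — the
inferential weight rests on the Cox $z$ and $p$. Exponential event times
(constant hazard, log-linear in treatments) are the generator's survival
model: the minimal process consistent with proportional hazards.

## The synthetic-experiment generator

`piper_sites()` encodes the emulated study conditions: five neotropical
sites; 12-plant plots; water addition crossed with the richness treatments
at three sites only; planted interspecific richness of 1, 2 or the site's
full pool; site pools of 12 (Costa Rica, Ecuador), 6 (Peru), 5 (Mogi) and 3
(Uaimii); 8–10 insect damage taxa per site with specialist-heavy communities
at Costa Rica and Ecuador; and experiment durations from roughly 1.4 to 2.8
years. Pool sizes at the two richest sites, the Uaimii minimum, the plot
size, and the taxon counts reflect the study design being emulated; the
remaining pools, two replicate plots per treatment cell, and a mean of six
leaves per plant (zero-truncated Poisson) are field-realistic conventions
fixed once — leaf counts per plant are simply not knowable from published
summaries.

The generator first simulates mortality (exponential times, right-censored
at the site duration), then recomputes realized richness from survivors, and
only survivors carry leaves. It has two modes. In **gaussian** mode the leaf
responses are drawn from the same truncated-normal models the package fits
(herbivory on [0, 100]; damage richness as a rounded truncated normal on
[0, n taxa]), so fitted models are essentially correctly specified and
coverage-based recovery tests are meaningful; drawn totals are split across
randomly chosen taxa so the long-format tables round-trip exactly. In
**mechanistic** mode each taxon attacks each leaf independently (Bernoulli
incidence with treatment-dependent logit) and removes a Gamma-distributed
leaf fraction; this mode produces skewed, zero-inflated damage like real
scoring data and is the robustness counterpoint to the gaussian mode.
Default effect magnitudes echo the scale of published multi-site *Piper*
results: site mean herbivory near 20% with large site spread, a water effect
of about −4 percentage points, about two damage taxa per leaf, and site
mortality spanning roughly 25–90%.

What the generator does *not* emulate: climate anomalies and seasonality,
spatial plot layout, leaf phenology and age structure, photographic scoring
error, and correlation between taxa beyond what treatments induce. Passing
recovery tests therefore demonstrate that the estimation machinery is
correct under the stated assumptions — not that those assumptions hold for
any particular field data set.

## Verification choices and problem sizes

The package's verification suite runs at desk scale, chosen so the full
suite completes in a few minutes on one CPU: conjugate testbeds for the
sampler (closed-form posteriors, 2% tolerance); twenty replicate
3-site × 24-plot gaussian experiments at 5,000 iterations/500 burn-in for
coverage of the cross-site coefficients (expecting ≥ 17/20 at nominal 95%);
twenty-seed PPC calibration and DIC-selection studies; and brute-force
oracles for the Cox partial likelihood and the DIC arithmetic. In the
recovery and calibration simulations the mortality process is held at a
fixed moderate level so that every realized design retains within-site
variation in all covariates; mortality-driven design degeneracy is a real
phenomenon (it is why realized richness is the covariate), but it is studied
separately from coefficient recovery. For the four-subject Cox oracle the
covariate is interleaved with the event order — a covariate perfectly
aligned with early events makes the partial likelihood monotone and the
maximizer infinite, which tests nothing.

## Known limitations

The normal likelihood is an approximation for bounded and count responses;
the PPC is the guard, not a proof. Site is the only hierarchical level —
plot and plant random effects are not modelled, following the cross-site
model's design. BSEMs assume independent equation errors and no latent
variables. The sampler is a random-walk method: posteriors with hundreds of
parameters or strong curvature would need many more iterations than the
defaults, and the funnel behaviour of hierarchy scales with few sites (three
in the recovery studies) makes the $\tau$ posteriors slow-mixing — the
hyper-means, which carry the scientific conclusions, mix well. DIC is
reported because it is the comparison statistic this workflow standardises
on; it is not a substitute for fully Bayesian model averaging.
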