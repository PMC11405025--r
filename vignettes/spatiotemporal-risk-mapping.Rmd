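---
title: "Spatiotemporal risk mapping for areal count panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal risk mapping for areal count panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

`arealrisk` analyses event counts aggregated to administrative areas
(municipalities) and calendar quarters, stratified by age group. For area
$i = 1, \dots, n$ and quarter $t = 1, \dots, T$ the count $y_{it}$ is modelled
with one of three likelihoods sharing the same expected count
$\lambda_{it} = \rho_{it}\,\epsilon_{it}$, where $\epsilon_{it}$ is the known
age-group population (the offset) and $\rho_{it}$ the incidence rate per
person-quarter:

$$
\nu_{it} = \log \rho_{it} = \alpha + \gamma_i + \delta_t + \beta_i I_{it}.
$$

* $\alpha$ — log baseline rate shared by all areas; `exp(alpha) * 1e5` is the
  *fixed-effect incidence per 100,000 person-quarters*.
* $\gamma_i \sim N(0, \tau_\gamma^{-1})$ — exchangeable (IID) spatial effects.
  Municipalities are treated as independent; no neighbourhood (CAR/BYM)
  structure is imposed, which is deliberate: the analysis this package
  implements assumes independence between areas, and the exceedance machinery
  below only needs the per-area posterior of $\gamma_i$.
* $\delta_t$ — temporal effect under a random-walk-of-order-two (RW2) prior:
  second differences $\delta_t - 2\delta_{t-1} + \delta_{t-2} \sim
  N(0, \tau_\delta^{-1})$. The RW2 density is improper in level and slope.
* $\beta_i \sim N(0, \tau_\beta^{-1})$ — per-area random slopes on a
  covariate $I_{it}$ (in the motivating application, fixed-internet points
  per inhabitant), giving each area its own credible interval.

The three likelihood families are Poisson ($y_{it} \sim
\text{Pois}(\lambda_{it})$); zero-inflated Poisson, which mixes a structural
point mass at zero with weight $\pi$ into the Poisson ($P(y=0) = \pi +
(1-\pi)e^{-\lambda}$); and the mean–scale negative binomial with
overdispersion parameter $\phi > 0$ and variance
$\lambda + \lambda^2/\phi$, recovering the Poisson as $\phi \to \infty$.

### Identification of the temporal effect

Because the RW2 prior is flat along $a + bt$, the level and slope of
$\delta$ are confounded with $\alpha$ (the model intentionally has no global
slope term). We therefore constrain $\delta$ to the subspace
$\{\sum_t \delta_t = 0,\ \sum_t t\,\delta_t = 0\}$. Rather than projecting
after every update, the sampler *parameterises* $\delta = B u$ where $B$ is
an orthonormal basis of that subspace ($T-2$ columns, orthogonal to the
constant and linear trend). Every stored draw then satisfies both
constraints exactly, proposals stay symmetric within the subspace, and no
level needs to be transferred back to $\alpha$ after the fact. The same
basis is used by the synthetic-data generator, so generated truths live in
the space the sampler explores and recovery experiments are well posed.

### Priors

The hyperpriors are diffuse but proper (see `default_priors()`):
$\tau_\gamma, \tau_\delta, \tau_\beta \sim \text{Gamma}(1,\ 5\times10^{-5})$,
$\alpha \sim N(0, 1000)$, $\operatorname{logit}\pi \sim N(-1, 1)$,
$\log\phi \sim N(0, 1)$. At surveillance sample sizes (hundreds of areas,
thousands of events) they contribute essentially no information; their role
is to keep every posterior proper. The precision priors are those commonly
used as defaults by latent-Gaussian inference software in disease mapping.

## Inference engine

`fit_panel()` runs an adaptive Metropolis-within-Gibbs sampler:

* $\tau_\gamma$, $\tau_\beta$: closed-form Gamma full conditionals
  (`gibbs_precision()`); $\tau_\delta$: Gamma conditional on the RW2
  quadratic form with rank $T - 2$.
* $\alpha$, each $u_k$ (temporal basis coordinate), $\operatorname{logit}\pi$
  and $\log\phi$: scalar adaptive random-walk Metropolis, target acceptance
  0.44, scales adapted in batches of 50 during burn-in and frozen afterwards
  to preserve ergodicity.
* $\gamma$ and $\beta$: all $n$ coordinates are proposed and accepted or
  rejected *simultaneously*, each against its own row of the likelihood.
  This is valid because the likelihood factorises over areas and the priors
  are IID, so the coordinates are conditionally independent given the rest;
  it makes the per-iteration cost $O(nT)$ instead of $O(n^2 T)$ and mixes
  better at $n$ in the tens to hundreds than a joint blocked proposal.
* A *level-interchange* move proposes $\alpha \to \alpha + d$,
  $\gamma \to \gamma - d$ jointly. The likelihood is invariant (only
  $\alpha + \gamma_i$ enters), so the move is accepted on the prior ratio
  alone; it decorrelates the intercept from the spatial field's mean, the
  one direction a coordinate-wise sampler traverses slowly.
* A joint *rescaling* move proposes $\beta \to \beta e^s$,
  $\tau_\beta \to \tau_\beta e^{-2s}$, which leaves the IID-prior quadratic
  form invariant and walks along the funnel that couples weakly identified
  slopes to their precision — without it, $\tau_\beta$ is the slowest-mixing
  parameter when the covariate effect is near zero.

Initialisation is crude moment matching: $\alpha$ at the log crude rate
(pseudocount 0.5 for empty panels), effects at zero, precisions at 10,
$\pi$ at 0.1, $\phi$ at 1. Chain $c$ of root seed $s$ uses seed
$(1000s + c) \bmod (2^{31}-1)$, making runs bit-reproducible. Defaults:
burn-in half of `n_iter`, thinning 5.

The `clamp` argument holds chosen components at their initial values. Its
main use is intercept-only reference fits, where the exact posterior is a
one-dimensional integral: the test suite compares such fits against direct
quadrature of the unnormalised posterior for all three families (with the
ZIP weight and NB scale clamped so the posterior stays one-dimensional).

`diagnose()` reports split-$\hat R$ (each chain halved) with flagging above
1.05, and an initial-positive-sequence autocorrelation estimate of the
effective sample size. Constant (e.g. clamped) parameters are reported as
undefined rather than erroring.

## Model comparison

`compute_dic()` and `compute_waic()` use full log-masses — every
$\log y!$ and normalising constant included — so criteria are comparable
*across* families, not just within one. The DIC plug-in deviance is
evaluated at the cell-wise posterior mean of $\lambda_{it}$ (with $\pi$
averaged on the logit scale and $\phi$ on the log scale); WAIC uses the
log-mean of per-draw masses per cell (log-sum-exp stabilised) minus the
sample variance (divisor $S-1$) of the per-draw log-masses.
`select_model()` picks the family with the lowest DIC per age group,
breaking exact ties toward the simpler family (Poisson, then negative
binomial, then ZIP) with a logged note.

## Reporting surfaces

* `exceedance_probabilities()` — per area, the fraction of draws with
  $\gamma_i > 0$, i.e. the posterior probability that the area's relative
  risk exceeds 1. Areas above the 0.8 threshold are classed high risk —
  the standard disease-mapping convention for the exceedance event, with
  the threshold a tunable argument. A state-level rollup uses the first two
  code digits.
* `fixed_effect_incidence()` — posterior summary of $e^\alpha \times 10^5$.
* `spatial_effect_surface()` — both honest map quantities: relative risk
  $E[e^{\gamma_i}]$ and combined incidence $E[e^{\alpha+\gamma_i}] \times
  10^5$; which one a map should show is an application choice, so both are
  provided.
* `temporal_effect_curve()` — posterior mean and 95% band of $e^{\delta_t}$.
* `covariate_significance()` — an area's slope is called nonzero when its
  0.025 and 0.975 posterior quantiles share a sign.
* `descriptive_incidence()` — model-free case counts and rates per 100,000
  by month/quarter/year, nationally or per area, from a line-list or a
  panel; national series are exact sums of area series.
* `export_maps()` — joins any per-area table onto a GeoJSON
  FeatureCollection by 5-digit code for choropleth rendering, reporting
  unmatched codes on both sides.

## Ingest conventions

The line-list ingest (`parse_line_list()`, `build_panel()`) follows fixed
conventions, each of which is a deliberate design choice:

* ages are taken as recorded at notification (the only age available per
  record); ages under 5 fall outside the six age groups (5–9, 10–14, 15–19,
  20–24, 25–59, >59) and are excluded with a log entry;
* quarters are indexed $t = 4(\text{year} - \text{origin}) +
  \lceil \text{month}/3 \rceil$ over a 12-quarter window by default;
* the population offset is held constant over quarters at the census value —
  no intercensal interpolation is attempted;
* municipality codes are matched as zero-padded 5-character strings to avoid
  4-versus-5-digit join bugs;
* covariate gaps are forward-filled within an area, then zero-filled, with
  a gap report;
* invalid rows go to a rejects table with reasons, and areas with zero group
  population are dropped and reported, so the cell counts always conserve
  the number of usable input records exactly.

## The synthetic-data generator

`simulate_truth()` / `simulate_panel()` generate panels with exactly the
structure the model assumes: IID Gaussian $\gamma$ and $\beta$, an RW2 draw
for $\delta$ (double cumulative sum of Gaussian innovations, then projected
onto the identified subspace — a projection that leaves the second
differences, and hence the innovation variance, untouched), log-uniform
area populations (municipality sizes are heavy-tailed), and counts from any
of the three families. An optional *dip* subtracts a smooth half-sine bump
from $\delta$ over a configurable quarter range before re-identification,
emulating a pandemic-era fall in notifications. Planted spatial effects
(`planted_gamma`) create known high-risk areas for calibration experiments.

Default scenario values — 60 areas, 12 quarters, populations 5,000–200,000,
$\alpha = -9$ (about 12 events per 100,000 person-quarters),
$\tau_\gamma = \tau_\beta = 4$, $\tau_\delta = 25$ — were chosen once to
mimic a middle-sized age-group panel of a national municipal surveillance
system: zero-heavy small counts in small municipalities, hundreds of events
in large ones.

Because the generator draws from the model's own families, passing recovery
tests shows the inference machinery is correct *under the model*; it says
nothing about misspecification on real data (unmodelled space-time
interaction, covariate measurement error, reporting delays), which is the
usual caveat of self-consistent simulation.

## Problem sizes and numerical choices

The validation experiments run at reduced desk scale, chosen as the package's
own test conditions: recovery and exceedance calibration use 20 replicates of
60 areas by 12 quarters (Poisson truth, 2 chains of 1,500 iterations);
model-selection power uses 20 replicates of 40 by 8 per truth family (single
chains of 2,000); the end-to-end script runs one 150-area study with all
three families. Degenerate inputs are handled explicitly: panels with fewer
than three quarters require the temporal effect clamped (RW2 needs three
points); constant chains yield flagged-undefined $\hat R$; zero-population
areas are dropped at ingest rather than producing infinite rates; the ZIP
zero branch is evaluated by log-sum-exp so large $\lambda$ cannot underflow
to $-\infty$ spuriously.

## Known limitations

* No spatially structured (CAR/BYM) prior and no space–time interaction —
  matching the model's independence assumption, not a gap to be filled by
  tuning.
* The MCMC engine targets desk-scale panels (up to a few hundred areas);
  a full 1,121-municipality national run is feasible but takes minutes per
  family rather than seconds.
* DIC/WAIC compare fit, not causal adequacy; the covariate-significance
  rule is an interval-sign call, not a multiplicity-adjusted test.
* The ZIP zero-inflation weight is structural and shared across cells; no
  covariates act on the zero process.
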