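---
title: "Modeling avian vagrancy against geomagnetic and solar activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling avian vagrancy against geomagnetic and solar activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Vagrancy — a migratory bird turning up far outside its species' expected
range for the date — is usually treated as a binary call made after the
fact. `vgm` instead treats it as a continuous quantity attached to every
capture record, and asks whether that quantity co-varies with disturbance
of the Earth's magnetic field (which migrating birds use for orientation)
and with solar radiofrequency noise (which can disrupt the radical-pair
magnetoreception mechanism). This vignette explains the index, the models,
the synthetic data that stand in for the real observational inputs, and the
numerical choices the package makes.

## The vagrancy index

For each species and week of the year, a weekly relative-abundance surface
says where the species is expected to be. We simulate `n` points (default
10,000) by drawing grid cells multinomially in proportion to abundance over
the cells inside the modeled range, jittering each point uniformly within
its cell. A capture record's raw vagrancy index is the mean great-circle
distance (haversine, Earth radius fixed at 6371 km) from the banding
location to its `k = 10` nearest simulated points. A bird captured in the
heart of its expected range sits on top of the cloud and scores tens of
kilometres; a genuine vagrant scores hundreds to thousands.

Design details that matter:

* One point cloud is simulated per species-week and shared by all records
  of that species-week, so the index is comparable within a species and
  the computation scales with species-weeks, not records.
* Records falling outside the modeled range (masked cells, or off the grid
  entirely) are flagged `excluded_out_of_range` and excluded from
  modeling rather than given an arbitrary value.
* A record that coincides with at least `k` cloud points would score
  exactly zero, which the gamma likelihood cannot accept; such values are
  floored to half the smallest positive index of that species. This is a
  pragmatic tie-break, not a statement about the data.
* Within-cell jitter is uniform in longitude/latitude rather than
  equal-area; at the default cell size (1 degree or finer) the distortion
  is far below the index's Monte Carlo noise.
* Week of year is day-of-year in blocks of seven, capped at 52, so the
  last one or two days of a year fold into week 52.

## Covariates

Both drivers enter the model as the rolling mean of the previous 21 days,
inclusive of the capture day (days *t*−20 … *t*). The window reflects the
latency between a disturbance event and the capture of a bird it
disoriented: shorter windows miss storms that happened mid-flight, much
longer windows dilute them. The first 20 days of a series carry no value
and records there are a hard error, not silently interpolated.

All covariates — the rolling indices, migration length, breeding latitude —
are z-standardized (population-SD convention, divide by *n*) before
modeling, so every effect below reads "per standard deviation". The
standardization is computed over record dates, not calendar days, and the
transform parameters are retained so effects can be mapped back to raw
index units.

Species traits come from the abundance surfaces themselves: 10,000 points
per week are pooled over the breeding (and non-breeding) season's weeks,
the arithmetic lon/lat centroid taken per season, and migration length is
the haversine distance between the two centroids. Arithmetic centroids are
adequate for mid-latitude ranges that do not span the antimeridian; inputs
that do are rejected rather than silently averaged across the wrap.

## Record inclusion and thinning

The filters mirror standard banding-data hygiene: wild captures only
(banding code 3), banding and encounter records but not recaptures (which
are inconsistently reported), location precision no worse than 10 km
(exactly 10 km is kept), capture date inside the species' seasonal
migration window and outside any taxonomic-indeterminacy window, and at
least 100 records per species per season (exactly 100 is kept). Unknown
age is kept in fall (the model imputes it) and dropped in spring via a
config switch, where age information is too sparse to impute.

Species with more than 20,000 season records are thinned to exactly
20,000 with per-row inclusion probability inversely proportional to the
number of that species' records in the row's year — dense years give up
records, sparse years keep theirs. Because every row of a year shares the
same weight, that law is equivalent to giving each year an equal share of
the cap, up to exhaustion of years smaller than the share (water-filling),
and drawing a simple random sample within each year; two years holding
30,000 and 10,000 records under a cap of 20,000 contribute 10,000 each.
Fractional shares are resolved by randomized rounding so the cap is hit
exactly.

## The hierarchical gamma models

The index is strictly positive, right-skewed, and its scale differs
between species purely for sampling reasons, so each species gets its own
gamma distribution. With records *j*, species *i*, years *t*:

$$y_j \sim \mathrm{Gamma}(shp_i,\; shp_i / e^{lp_j}),$$

a shape/rate parameterization chosen so that the mean of $y_j$ is exactly
$e^{lp_j}$. The single-driver form is

$$lp_j = \alpha_{t,i} + \beta_{t,i} X_j + \lambda_i\, age_j +
\nu_i\, age_j X_j,$$

with year-within-species random intercepts and slopes, species-level age
offsets ($age_j$ is 1 for birds in their first year), and a trait-level
regression for the species sensitivities:

$$\mu_{\beta_i} \sim N(\delta_i, \sigma_\delta), \qquad
\delta_i = \omega + \psi\,\mathrm{migration\ length}_i +
\eta\,\mathrm{breeding\ latitude}_i.$$

$\omega$ is the assemblage-wide effect of the driver at mean trait values;
$\psi$ and $\eta$ ask whether long-distance or high-latitude migrants are
more sensitive. The interaction form drops the age terms and fits both
drivers at once with species-level slopes and a product term,

$$lp_j = \alpha_{t,i} + \beta_i X_{1j} + \theta_i X_{2j} +
\omega_i X_{1j} X_{2j},$$

each slope family hierarchically normal across species. (In the
single-driver form the year-level slope $\beta_{t,i}$ is used; the
interaction form uses species-level $\beta_i$ — the two structures the
respective hierarchies define.)

**Age imputation.** Unknown-age records are retained by treating their age
as a latent Bernoulli draw with species-level prevalence
$\pi_i \sim \mathrm{Beta}(2,2)$. The sampler (JAGS) handles discrete
latent variables natively, so the latent-draw formulation is used rather
than analytically marginalizing the two-component mixture; the posterior
is identical either way, and the latent form keeps the model code legible.

**Priors.** Slope-level means ($\omega, \psi, \eta, \mu_\lambda, \mu_\nu$,
and the interaction-model means) are Normal(0, 1) on the standardized
scale — weakly informative when effects per SD are a few percent.
Hierarchical SDs are half-Normal(0, 1). Intercept-level means
($\mu_\gamma$, and the interaction model's grand intercept) are
Normal(0, 10), because the log-scale intercept sits wherever the index's
scale puts it (around 5 for a ~150 km typical index) and a unit-scale
prior would fight the data. The shape mean is half-Normal(0, 5), species
shapes truncated-normal above zero. All are package choices — stated here
because nothing in the scientific problem pins them — and are deliberately
wide relative to every effect the tests exercise.

**Sampling.** Models are fit with JAGS via `rjags`, centered
parameterization throughout (JAGS's conditional samplers do not suffer the
funnel geometry that motivates non-centering under Hamiltonian Monte
Carlo). Convergence is assessed with split-chain R-hat (accept at most
1.05) and effective sample size (at least 100) on the top-level
parameters; a failing fit is returned flagged, with a warning, so callers
can lengthen chains rather than silently trust it.

**Derived quantities.** Effects are reported as posterior medians with
equal-tailed 95% credible intervals and a directional tail probability
(share of draws above zero when the median is positive, below otherwise).
Because the link is a log, an effect $b$ per SD maps to a
$100(e^{b\,\Delta}-1)$ percent change in predicted median vagrancy for a
$\Delta$-SD covariate rise — `predicted_change_percent()`. Bayesian R² for
the interaction model follows the variance-ratio convention: per draw and
species, the covariate part $g_j = \beta_i X_{1j} + \theta_i X_{2j} +
\omega_i X_{1j}X_{2j}$ and residual $y_j - g_j$ give
$V_g / (V_g + V_\varepsilon)$; species get their posterior median and the
cross-species summary is the median of those medians. The ratio is only
meaningful when $y$ and $g$ share a scale: the covariate terms live on the
log scale, so for gamma-distributed indices the residual should be formed
against log-vagrancy (as the acceptance script does); `bayesian_r2()`
itself is scale-agnostic and uses whatever response it is given. Posterior
predictive checks simulate replicate datasets from the fitted gamma
likelihood and compare per-species statistics (mean, SD, max, tail
proportion) between replicated and observed data.

## The synthetic world

Real inputs — continental banding archives, weekly abundance rasters,
observatory index downloads, published phylogenies — are replaced by a
generator whose defaults are chosen once to be realistic for the system:

* **Abundance surfaces** are truncated Gaussian bumps (bandwidth 3°,
  masked beyond 4 bandwidths) on a 1° grid spanning roughly the eastern
  United States; each species' centroid interpolates linearly from its
  breeding centre to its non-breeding centre across the fall weeks
  (32–45) and back in spring (weeks 14–23), with stationary breeding
  (25–28) and non-breeding (1–4) seasons.
* **Index series** are daily AR(1) noise (lag-1 coefficient 0.8) around a
  sinusoid with an ~11-year period, floored at zero because physical
  disturbance indices are nonnegative; baselines (13 for the geomagnetic
  series, 56 for the solar series) sit near the observed long-run means
  of the Ap index and the American sunspot number. The two series share
  the sinusoid phase, which induces the positive cross-correlation the
  real indices show; the pipeline reports the realized Pearson
  correlation as a diagnostic.
* **Records** come in two modes. `model_level` draws each record's
  vagrancy directly from the generative gamma law with the full
  hierarchy (default truth: ω = 0.11, ψ = 0.04, η = 0, λ = 0.05, ν = 0,
  log-scale intercept 5), which makes statistical recovery exact and
  fast. `spatial` places the record on the landscape instead — a base
  location from the species-week surface displaced by an exponential
  distance with mean $e^{lp}$ km in a uniform direction — exercising the
  whole geometric pipeline. The displacement law is a stand-in chosen for
  its monotone link between $lp$ and expected displacement; no mechanistic
  displacement model is implied by the science, and nothing downstream
  depends on its exact form.
* **Ages** are Bernoulli per species (prevalence uniform on 0.35–0.65)
  and masked to unknown with probability 0.3 by default, in the range
  seen in real fall banding data.
* **Phylogenies** are Yule trees; trait values are Brownian realizations
  along branches (phylogenetic signal, Blomberg's K ≈ 1) or i.i.d. normal
  (no signal, K ≪ 1).

What the generator does *not* emulate: realistic range shapes, observer
effort gradients, spatial clustering of banding stations, taxonomy-driven
record ambiguity, and measurement error in the abundance surfaces
themselves. Passing tests therefore demonstrate that the machinery is
correct and calibrated under the stated generative assumptions, not that
any particular effect exists in real data.

## Test problem sizes

The recovery and calibration suites deliberately use compact worlds so the
full test suite runs comfortably on a single CPU: 20 replicates of
15 species × 6 years × 30 records per species-year for parameter
recovery (thresholds 17/20 for ω and λ, 15/20 for the weaker-identified
ψ), 40 replicates of 10 × 5 × 25 for null-sign calibration, and three
replicate pairs for the imputation comparison. Coverage of a 95% credible
interval is scale-free, so these thresholds do not depend on the world
size; only the interval widths do.

## Known limitations

* Arithmetic lon/lat centroids and uniform jitter are mid-latitude
  approximations; neither is suitable near the poles or the antimeridian.
* The gamma likelihood excludes exact zeros; the flooring rule above is a
  convention, and datasets dominated by zero distances would need a
  hurdle component instead.
* Single-chain replicate fits in the test suites trade R-hat diagnostics
  for speed; the user-facing default is two chains, and any serious
  analysis should use four.
* Blomberg's K is computed by `picante::Kcalc`; the package adds tip
  matching, tree-set bootstrapping and simulation scaffolding, not a new
  estimator.
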