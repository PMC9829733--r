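# vgm — avian vagrancy under geomagnetic disturbance and solar activity

Migratory birds orient partly by the Earth's magnetic field. When that
field is disturbed — or when solar radiofrequency noise interferes with
the magnetoreception mechanism itself — do more birds end up far outside
their expected range? `vgm` provides the full analytical pipeline for
asking that question with banding (ringing) records: a continuous
**vagrancy index** for every capture, rolling environmental covariates,
and **hierarchical Bayesian gamma models** of the index against
geomagnetic and solar activity, plus the post-hoc tests (phylogenetic
signal, diel strategy) that probe the fitted species sensitivities. It is
aimed at movement ecologists and macroecologists working with banding-scale
occurrence data and weekly abundance products.

## The quantities at the core

**Vagrancy index.** For species *i* in week *w*, simulate 10,000 points
proportional to the species' weekly relative-abundance surface; a record's
index *y* is the mean haversine distance (km) to its *k* = 10 nearest
points. Low values mean "where the species should be", high values mean
spatiotemporal rarity.

**Model.** With records *j*, species *i*, years *t*, and X the 21-day
rolling mean of the driver index (z-standardized):

    y_j ~ Gamma(shp_i, shp_i / exp(lp_j))
    lp_j = alpha_ti + beta_ti * X_j + lambda_i * age_j + nu_i * age_j * X_j
    mu_beta_i ~ N(delta_i, sigma_delta)
    delta_i = omega + psi * migration_length_i + eta * breeding_latitude_i

so `omega` is the assemblage-wide effect per SD of the driver, and `psi`,
`eta` let sensitivity vary with how far and how high-latitude a species
migrates. Unknown ages are imputed as latent Bernoulli draws with
species-level prevalence. A second, interaction form fits both drivers and
their product. Everything is sampled with JAGS (`rjags`), summarized as
posterior medians, 95% credible intervals, and directional tail
probabilities, with Bayesian R² and posterior predictive checks on top.

Because real banding archives and abundance rasters cannot ship with a
package, `vgm` includes a first-class synthetic-world generator
(`gen_world()`, `gen_banding_records()`, `gen_phylogeny_traits()`) with
known ground truth, which the test suite uses to verify parameter
recovery, null calibration and imputation behaviour end to end.

## Worked example

Generate a synthetic world with known truth, draw records from the
generative gamma model, and re-estimate the effects:

```r
library(vgm)

world  <- gen_world(world_config(n_species = 15, n_years = 6, seed = 1))
truth  <- truth_params()          # omega = 0.11, psi = 0.04, lambda = 0.05
rec    <- gen_banding_records(world, truth, n_per_species_year = 30,
                              mode = "model_level", seed = 2)
rc     <- join_covariates(rec, rolling_mean_21(world$geomag),
                          rolling_mean_21(world$solar))
spec   <- model_spec(chains = 2, n_adapt = 500, n_burn = 1500,
                     n_iter = 2000, seed = 4)
inputs <- build_inputs(rc, world$traits, spec)
fit    <- fit_vagrancy_model(spec, inputs)
fit
#> vgm hierarchical gamma fit (single_driver, fall): 15 species, 6 years
#> 2 chains x 2000 kept iterations; converged: FALSE
#>   omega      median   0.1328  95% CrI (  0.0806,   0.1902)  p(>0) = 1.00  Rhat 1.044
#>   psi        median   0.0022  95% CrI ( -0.0614,   0.0767)  p(>0) = 0.53  Rhat 1.055
#>   eta        median   0.0249  95% CrI ( -0.0423,   0.0836)  p(>0) = 0.79  Rhat 1.013
#>   mu_lambda  median   0.0435  95% CrI ( -0.0125,   0.1061)  p(>0) = 0.92  Rhat 1.020
#>   mu_nu      median  -0.0388  95% CrI ( -0.1069,   0.0330)  p(<0) = 0.86  Rhat 1.031
#>   mu_gamma   median   4.8913  95% CrI (  4.7453,   5.0335)  p(>0) = 1.00  Rhat 1.002
```

The printed `omega` is the assemblage-wide effect of the geomagnetic
driver per SD of 21-day disturbance: the 95% CrI (0.08, 0.19) recovers the
generative value 0.11 with decisive sign evidence, while the weaker trait
and age effects remain uncertain at this deliberately small problem size.
(`converged: FALSE` here is the strict effective-sample-size gate, not
R-hat; the fit warns rather than hides it — lengthen the chains for a
real analysis.) For records placed on the landscape instead, run
`mode = "spatial"` and index them against the abundance surfaces with
`compute_vagrancy_table(rec, world$surfaces)` before joining covariates.

Translate an effect to an interpretable change with the log-link
identity:

```r
predicted_change_percent(0.109, 2)
#> [1] 24.36886
```

i.e. a two-SD rise in 21-day geomagnetic disturbance at an effect of
0.109 per SD predicts a ~24% increase in median vagrancy.

Post-hoc, test whether fitted species sensitivities carry phylogenetic
signal or differ by diel migration strategy:

```r
sens <- species_sensitivity(fit)
pt   <- gen_phylogeny_traits(15, "brownian", seed = 5)
blombergs_k(setNames(sens$sensitivity, sens$species_code), pt$tree)
diel_comparison(sens, world$traits)
```

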