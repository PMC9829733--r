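# Shared small synthetic world, built once per test run. Five species over
# three years on a 1-degree grid; big enough to exercise every code path,
# small enough to keep the suite fast.
tiny_world <- gen_world(world_config(n_species = 5, n_years = 3, seed = 42))

# Records drawn at model level from the generative gamma model, with the
# default effect sizes and ~30% unknown age.
tiny_records <- gen_banding_records(
  tiny_world, truth_params(), n_per_species_year = 25,
  mode = "model_level", seed = 7
)

# Covariate-joined copy used by the model tests.
tiny_with_cov <- join_covariates(
  tiny_records,
  rolling_mean_21(tiny_world$geomag),
  rolling_mean_21(tiny_world$solar)
)

withr_tempfile <- function() withr::local_tempfile(.local_envir = parent.frame())
withr_tempdir <- function() withr::local_tempdir(.local_envir = parent.frame())

# A deliberately tiny fit used by several model tests; single chain, short.
fit_tiny <- function(seed = 11, ...) {
  spec <- model_spec(chains = 1, n_adapt = 150, n_burn = 100, n_iter = 300,
                     seed = seed, ...)
  inputs <- build_inputs(tiny_with_cov, tiny_world$traits, spec)
  list(spec = spec, inputs = inputs,
       fit = suppressWarnings(fit_vagrancy_model(spec, inputs)))
}
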