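# Synthetic-world generator: surfaces, index series, record generation,
# phylogenies, determinism.

test_that("weekly surfaces normalize to unit mass over unmasked cells", {
  for (key in sample(names(tiny_world$surfaces), 10)) {
    s <- tiny_world$surfaces[[key]]
    expect_equal(sum(s$abundance[s$mask]), 1, tolerance = 1e-12)
    expect_true(all(s$abundance[!s$mask] == 0))
  }
})

test_that("a constant drift schedule keeps weekly centroids identical", {
  w <- gen_world(world_config(n_species = 2, n_years = 2, drift = "constant",
                              seed = 3))
  keys <- grep("^SP01_", names(w$surfaces), value = TRUE)
  ab <- sapply(keys, function(k) w$surfaces[[k]]$abundance)
  expect_true(all(apply(ab, 1, function(r) diff(range(r)) == 0)))
})

test_that("drifting surfaces move the abundance centroid between centres", {
  s_first <- tiny_world$surfaces[["SP01_w32"]]
  s_last <- tiny_world$surfaces[["SP01_w45"]]
  lat_first <- sum(s_first$lat * s_first$abundance)
  lat_last <- sum(s_last$lat * s_last$abundance)
  expect_gt(lat_first, lat_last) # fall migration moves south
})

test_that("AR1 = 0 with a flat cycle yields white-noise indices", {
  w <- gen_world(world_config(n_species = 2, n_years = 6, ar1 = 0,
                              cycle_amp = 0, seed = 9))
  for (series in list(w$geomag, w$solar)) {
    v <- series$value
    r1 <- stats::cor(v[-1], v[-length(v)])
    expect_lt(abs(r1), 3 / sqrt(length(v)))
  }
})

test_that("AR1 noise produces the requested lag-1 autocorrelation", {
  w <- gen_world(world_config(n_species = 2, n_years = 6, ar1 = 0.8,
                              cycle_amp = 0, seed = 10))
  v <- w$geomag$value
  r1 <- stats::cor(v[-1], v[-length(v)])
  expect_gt(r1, 0.7)
  expect_true(all(v >= 0))
})

test_that("degenerate grids are rejected", {
  expect_error(world_config(lon_range = c(0, 0.5), lat_range = c(0, 0.5),
                            cell_deg = 1), "degenerate grid")
})

test_that("model-level records draw y from the gamma law with mean exp(lp)", {
  # all hierarchy SDs zero and no covariate effect -> lp is exactly mu_gamma
  tr <- truth_params(omega = 0, psi = 0, eta = 0, lambda = 0, nu = 0,
                     mu_gamma = 5, sigma_gamma = 0, sigma_alpha = 0,
                     sigma_delta = 0, sigma_beta = 0, sigma_lambda = 0,
                     sigma_nu = 0, shape_range = c(2, 2))
  rec <- gen_banding_records(tiny_world, tr, n_per_species_year = 200,
                             mode = "model_level", seed = 21)
  ratio <- rec$vagrancy_km / exp(5)
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("null effects leave y uncorrelated with the covariate", {
  tr <- truth_params(omega = 0, psi = 0, eta = 0, lambda = 0, nu = 0,
                     sigma_delta = 0, sigma_beta = 0, sigma_nu = 0)
  rec <- gen_banding_records(tiny_world, tr, n_per_species_year = 100,
                             mode = "model_level", seed = 22)
  rc <- join_covariates(rec, rolling_mean_21(tiny_world$geomag),
                        rolling_mean_21(tiny_world$solar))
  r <- stats::cor(log(rc$vagrancy_km), rc$geomag_21)
  expect_lt(abs(r), 3 / sqrt(nrow(rc)))
})

test_that("age masking respects age_missing_prob boundaries", {
  rec_all <- gen_banding_records(tiny_world,
                                 truth_params(age_missing_prob = 1),
                                 n_per_species_year = 10, seed = 5)
  expect_true(all(rec_all$age_class == "unknown"))
  rec_none <- gen_banding_records(tiny_world,
                                  truth_params(age_missing_prob = 0),
                                  n_per_species_year = 10, seed = 5)
  expect_true(all(rec_none$age_class %in% c("adult", "young")))
})

test_that("invalid generation parameters are rejected", {
  expect_error(gen_banding_records(tiny_world, truth_params(),
                                   n_per_species_year = 0), "positive")
  expect_error(truth_params(shape_range = c(-1, 2)))
  expect_error(truth_params(age_missing_prob = 1.5))
})

test_that("identical seeds give identical worlds and records", {
  w1 <- gen_world(world_config(n_species = 3, n_years = 2, seed = 77))
  w2 <- gen_world(world_config(n_species = 3, n_years = 2, seed = 77))
  expect_identical(w1$geomag$value, w2$geomag$value)
  expect_identical(w1$surfaces[["SP02_w40"]]$abundance,
                   w2$surfaces[["SP02_w40"]]$abundance)
  r1 <- gen_banding_records(w1, truth_params(), 10, seed = 3)
  r2 <- gen_banding_records(w2, truth_params(), 10, seed = 3)
  expect_identical(r1, r2)
})

test_that("Yule phylogenies have the requested tips and honest errors", {
  pt <- gen_phylogeny_traits(12, "brownian", seed = 4)
  expect_equal(length(pt$tree$tip.label), 12)
  expect_equal(sort(names(pt$values)), sort(pt$tree$tip.label))
  wn <- gen_phylogeny_traits(12, "white_noise", seed = 4)
  expect_equal(length(wn$values), 12)
  expect_error(gen_phylogeny_traits(3), "at least 4")
})

test_that("spatial mode displaces records relative to model-level locations", {
  tr <- truth_params()
  rec <- gen_banding_records(tiny_world, tr, n_per_species_year = 20,
                             mode = "spatial", seed = 31)
  expect_false("vagrancy_km" %in% names(rec))
  expect_true(all(abs(rec$lat) <= 90))
  # larger lp must mean larger expected displacement: check via hidden truth
  truth <- attr(rec, "truth")
  expect_equal(length(truth$lp), nrow(rec))
})
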