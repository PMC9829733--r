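# Hierarchical gamma model: input assembly, sampling, summaries, R2, PPC.

test_that("build_inputs produces dense indices and honest errors", {
  spec <- model_spec()
  inp <- build_inputs(tiny_with_cov, tiny_world$traits, spec)
  expect_equal(inp$n_species, 5)
  expect_equal(inp$n_years, 3)
  expect_equal(inp$n_species * inp$n_years, 15) # alpha has one cell per (t,i)
  expect_equal(length(inp$y), nrow(tiny_with_cov))
  # unknown-age rows are retained when imputation is on
  expect_true(anyNA(inp$age))
  expect_equal(mean(inp$X), 0, tolerance = 1e-10)

  # a zero response points to the flooring step
  bad <- tiny_with_cov
  bad$vagrancy_km[3] <- 0
  expect_error(build_inputs(bad, tiny_world$traits, spec), "floored")

  # a species confined to one year is flagged, not rejected
  lop <- tiny_with_cov
  lop <- lop[!(lop$species_code == "SP01" &
                 strftime(lop$date, "%Y") != "2000"), ]
  expect_warning(build_inputs(lop, tiny_world$traits, spec), "SP01")

  # dropping unknown ages on request
  spec2 <- model_spec(impute_age = FALSE)
  inp2 <- build_inputs(tiny_with_cov, tiny_world$traits, spec2)
  expect_false(anyNA(inp2$age))
  expect_lt(length(inp2$y), length(inp$y))
})

test_that("the interaction spec rejects age terms and builds two covariates", {
  expect_error(model_spec(form = "interaction", include_age_terms = TRUE),
               "excludes age")
  spec <- model_spec(form = "interaction")
  inp <- build_inputs(tiny_with_cov, spec = spec)
  expect_equal(length(inp$X1), length(inp$X2))
  expect_equal(stats::sd(inp$X1) * sqrt((length(inp$X1) - 1) / length(inp$X1)),
               1, tolerance = 1e-10)
})

test_that("summaries report median, CrI and directional tail probability", {
  draws <- cbind(a = c(-1, 0, 1), b = c(1, 2, 3))
  s <- summarize_draws(draws, "a")
  expect_equal(s$median, 0)
  s_b <- summarize_draws(draws, "b")
  expect_equal(s_b$tail_prob, 1)
  expect_error(summarize_draws(draws, "zz"), "available")

  set.seed(1)
  norm <- cbind(x = stats::rnorm(40000))
  s_n <- summarize_draws(norm, "x")
  expect_equal(s_n$lower, -1.96, tolerance = 0.05)
  expect_equal(s_n$upper, 1.96, tolerance = 0.05)
})

test_that("predicted change follows the log link", {
  expect_equal(round(predicted_change_percent(0.109, 2)), 24)
  expect_equal(predicted_change_percent(0, 2), 0)
  expect_equal(predicted_change_percent(-0.023, 2), -4.496, tolerance = 1e-3)
})

test_that("a short fit returns draws, diagnostics and species sensitivities", {
  res <- fit_tiny()
  fit <- res$fit
  expect_s3_class(fit, "vgm_fit")
  expect_equal(nrow(fit$draws), 300)
  expect_true(all(c("omega", "psi", "eta", "mu_lambda") %in%
                    colnames(fit$draws)))
  expect_true(all(fit$draws[, sprintf("shp[%d]", 1:5)] > 0))
  sens <- species_sensitivity(fit)
  expect_equal(sens$species_code, fit$species_codes)
  expect_true(is.finite(fit$ess["omega"]))
  expect_output(print(fit), "hierarchical gamma fit")
})

test_that("with a null covariate the global effect stays at its prior", {
  # X identically zero: the likelihood carries no information about omega,
  # whose marginal posterior should remain close to its Normal(0,1) prior
  set.seed(2)
  n <- 200
  inp <- structure(list(
    y = stats::rgamma(n, 2, 2 / exp(5)),
    sp = rep(1:2, each = n / 2), yr = rep(rep(1:2, each = n / 4), 2),
    age = rep(0, n), X = rep(0, n),
    species_codes = c("A", "B"), years = c(2001, 2002),
    n_species = 2, n_years = 2
  ), class = "model_inputs")
  spec <- model_spec(include_age_terms = FALSE, trait_regression = FALSE,
                     chains = 1, n_adapt = 200, n_burn = 100, n_iter = 800,
                     seed = 4)
  fit <- suppressWarnings(fit_vagrancy_model(spec, inp))
  o <- fit$draws[, "omega"]
  # prior sd is 1: an identified fit shrinks this to ~0.05, an uninformative
  # covariate must not (the chain mixes slowly here, so bounds are loose)
  expect_gt(stats::sd(o), 0.6)
  expect_lt(abs(mean(o)), 0.5)
})

test_that("Bayesian R2 respects its bounds and limiting cases", {
  ns <- 3
  n <- 120
  set.seed(6)
  inp <- structure(list(
    y = NULL, sp = rep(1:ns, each = n / ns),
    X1 = stats::rnorm(n), X2 = stats::rnorm(n),
    species_codes = c("A", "B", "C"), n_species = ns
  ), class = "model_inputs")
  draws <- matrix(
    rep(c(rep(0.8, ns), rep(-0.5, ns), rep(0.3, ns)), each = 4), nrow = 4
  )
  colnames(draws) <- c(sprintf("beta[%d]", 1:ns), sprintf("theta[%d]", 1:ns),
                       sprintf("omega_i[%d]", 1:ns))
  g <- 0.8 * inp$X1 - 0.5 * inp$X2 + 0.3 * inp$X1 * inp$X2

  # residuals identically zero -> R2 = 1
  inp$y <- g
  r <- bayesian_r2(draws, inp)
  expect_equal(r$overall, 1)
  expect_true(all(r$per_species$r2 == 1))

  # zero effects -> R2 = 0 regardless of y
  zero <- draws * 0
  colnames(zero) <- colnames(draws)
  inp$y <- g + stats::rnorm(n)
  r0 <- bayesian_r2(zero, inp)
  expect_true(all(r0$per_species$r2 == 0))

  # generic case stays within [0, 1]
  r_mid <- bayesian_r2(draws, inp)
  expect_true(all(r_mid$per_species$r2 >= 0 & r_mid$per_species$r2 <= 1))
})

test_that("posterior predictive checks are calibrated on well-specified data", {
  res <- fit_tiny(seed = 15)
  ppc <- posterior_predictive_check(res$fit, res$inputs, statistic = "mean",
                                    n_draws = 120)
  expect_equal(nrow(ppc), 5)
  expect_true(all(ppc$ppc_tail_prob >= 0 & ppc$ppc_tail_prob <= 1))
  # data were generated from the model family: no species should sit in an
  # extreme tail for the mean statistic
  expect_true(all(ppc$ppc_tail_prob > 0.01 & ppc$ppc_tail_prob < 0.99))
})

test_that("posterior predictive checks flag contaminated data", {
  res <- fit_tiny(seed = 16)
  inp <- res$inputs
  contaminated <- inp
  big <- order(inp$y, decreasing = TRUE)[1]
  contaminated$y[big] <- inp$y[big] * 50 # one absurd outlier per dataset
  ppc <- posterior_predictive_check(res$fit, contaminated, statistic = "max",
                                    n_draws = 120)
  expect_lt(min(ppc$ppc_tail_prob), 0.05)
})
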