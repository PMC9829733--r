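# Hierarchical Bayesian gamma regression of the vagrancy index on rolling
# geomagnetic/solar covariates, fit with JAGS. Two forms:
#
# single_driver (one covariate X, with age terms and Bayesian age imputation):
#   y_j ~ gamma(shp_i, shp_i / exp(lp_j))
#   lp_j = alpha_{t,i} + beta_{t,i} X_j + lambda_i age_j + nu_i age_j X_j
#   alpha_{t,i} ~ N(gamma_i, sigma_alpha);  beta_{t,i} ~ N(mu_beta_i, sigma_beta)
#   lambda_i ~ N(mu_lambda, sigma_lambda);  nu_i ~ N(mu_nu, sigma_nu)
#   gamma_i ~ N(mu_gamma, sigma_gamma)
#   mu_beta_i ~ N(delta_i, sigma_delta)
#   delta_i = omega + psi migration_length_i + eta breeding_latitude_i
#   unknown age_j ~ Bernoulli(pi_i), imputed within the sampler
#
# interaction (two covariates and their product, no age terms):
#   lp_j = alpha_{t,i} + beta_i X1_j + theta_i X2_j + omega_i X1_j X2_j
#   beta_i ~ N(mu_beta, sigma_beta); theta_i ~ N(mu_theta, sigma_theta)
#   omega_i ~ N(mu_omega, sigma_omega)
#   alpha_{t,i} ~ N(mu_alpha_i, sigma_alpha); mu_alpha_i ~ N(gamma, sigma_mu_alpha)

#' Model specification
#'
#' @param form `"single_driver"` (one covariate, age terms, trait-level
#'   regression of species sensitivity) or `"interaction"` (geomagnetic and
#'   solar covariates plus their product; age terms are excluded in this
#'   form for tractability).
#' @param driver covariate for the single-driver form: `"geomag"` or
#'   `"solar"`.
#' @param season label only (`"fall"`/`"spring"`), carried into summaries.
#' @param include_age_terms fit the age intercept/slope offsets
#'   (single-driver only).
#' @param impute_age keep unknown-age rows and impute their age as a latent
#'   Bernoulli per species; if `FALSE`, unknown-age rows are dropped in
#'   [build_inputs()].
#' @param trait_regression model species sensitivity as a linear function of
#'   standardized migration length and breeding latitude.
#' @param chains,n_adapt,n_burn,n_iter,thin sampler settings.
#' @param seed integer seed (per-chain RNGs are derived from it).
#' @return a `model_spec` list.
#' @export
model_spec <- function(form = c("single_driver", "interaction"),
                       driver = c("geomag", "solar"),
                       season = "fall",
                       include_age_terms = (form[1] == "single_driver"),
                       impute_age = TRUE,
                       trait_regression = TRUE,
                       chains = 2, n_adapt = 300, n_burn = 200,
                       n_iter = 600, thin = 1, seed = 1) {
  form <- match.arg(form)
  driver <- match.arg(driver)
  if (form == "interaction" && include_age_terms) {
    stop("the interaction form excludes age terms")
  }
  structure(list(
    form = form, driver = driver, season = season,
    include_age_terms = include_age_terms, impute_age = impute_age,
    trait_regression = trait_regression,
    chains = chains, n_adapt = n_adapt, n_burn = n_burn,
    n_iter = n_iter, thin = thin, seed = seed
  ), class = "model_spec")
}

#' Assemble model inputs from a vagrancy table with covariates
#'
#' Drops out-of-range rows, standardizes the covariate(s) over the record
#' rows (population SD, transform retained), builds dense species/year
#' indices, encodes age as 0 = adult, 1 = young, `NA` = unknown, and joins
#' standardized species traits.
#'
#' @param records vagrancy table with `vagrancy_km`, `geomag_21`/`solar_21`
#'   columns (see [join_covariates()]).
#' @param traits trait table with `migration_length_km` and
#'   `breeding_latitude_deg` (required when the spec uses the trait
#'   regression).
#' @param spec a [model_spec()].
#' @return a `model_inputs` list (`y`, `sp`, `yr`, covariates, `age`,
#'   `species_codes`, `years`, trait z-scores, standardization transforms).
#' @export
build_inputs <- function(records, traits = NULL, spec = model_spec()) {
  if ("excluded_out_of_range" %in% names(records)) {
    records <- records[!records$excluded_out_of_range, , drop = FALSE]
  }
  if (!"vagrancy_km" %in% names(records)) {
    stop("records need a vagrancy_km column; run compute_vagrancy_table()")
  }
  if (any(is.na(records$vagrancy_km))) {
    stop("NA vagrancy values in modeled rows")
  }
  if (any(records$vagrancy_km <= 0)) {
    stop("vagrancy_km must be positive (zeros are floored upstream in ",
         "compute_vagrancy_table)")
  }
  age <- c(adult = 0, young = 1, unknown = NA)[records$age_class]
  if (spec$include_age_terms && !spec$impute_age) {
    keep <- !is.na(age)
    records <- records[keep, , drop = FALSE]
    age <- age[keep]
  }
  species_codes <- sort(unique(records$species_code))
  years <- sort(unique(as.integer(strftime(records$date, "%Y"))))
  if (length(species_codes) < 2 || length(years) < 2) {
    stop("need at least 2 species and 2 years")
  }
  sp <- match(records$species_code, species_codes)
  yr <- match(as.integer(strftime(records$date, "%Y")), years)
  single_year <- vapply(seq_along(species_codes), function(i) {
    length(unique(yr[sp == i])) == 1
  }, logical(1))
  if (any(single_year)) {
    warning("species with records from a single year (year effects weakly ",
            "identified): ", paste(species_codes[single_year], collapse = ", "))
  }

  out <- list(
    y = records$vagrancy_km, sp = sp, yr = yr, age = unname(age),
    species_codes = species_codes, years = years,
    n_species = length(species_codes), n_years = length(years)
  )
  if (spec$form == "single_driver") {
    col <- paste0(spec$driver, "_21")
    if (!col %in% names(records)) stop("records lack covariate column ", col)
    zx <- standardize(records[[col]])
    out$X <- zx$z
    out$x_transform <- zx[c("mean", "sd")]
  } else {
    for (nm in c("geomag_21", "solar_21")) {
      if (!nm %in% names(records)) stop("records lack covariate column ", nm)
    }
    z1 <- standardize(records$geomag_21)
    z2 <- standardize(records$solar_21)
    out$X1 <- z1$z
    out$X2 <- z2$z
    out$x_transform <- list(geomag = z1[c("mean", "sd")],
                            solar = z2[c("mean", "sd")])
  }
  if (spec$form == "single_driver" && spec$trait_regression) {
    if (is.null(traits)) stop("trait_regression requires a traits table")
    ti <- match(species_codes, traits$species_code)
    if (any(is.na(ti))) {
      stop("species missing from traits: ",
           paste(species_codes[is.na(ti)], collapse = ", "))
    }
    out$mig_z <- standardize(traits$migration_length_km[ti])$z
    out$blat_z <- standardize(traits$breeding_latitude_deg[ti])$z
  }
  class(out) <- "model_inputs"
  out
}

jags_model_single <- function(age_terms, trait_regression) {
  lp_age <- if (age_terms) {
    " + lambda[sp[j]] * age[j] + nu[sp[j]] * age[j] * X[j]"
  } else ""
  age_block <- if (age_terms) "
    age[j] ~ dbern(prev[sp[j]])" else ""
  age_sp <- if (age_terms) "
    lambda[i] ~ dnorm(mu_lambda, tau_lambda)
    nu[i] ~ dnorm(mu_nu, tau_nu)
    prev[i] ~ dbeta(2, 2)" else ""
  age_priors <- if (age_terms) "
  mu_lambda ~ dnorm(0, 1)
  mu_nu ~ dnorm(0, 1)
  sd_lambda ~ dnorm(0, 1) T(0,); tau_lambda <- pow(sd_lambda, -2)
  sd_nu ~ dnorm(0, 1) T(0,); tau_nu <- pow(sd_nu, -2)" else ""
  delta <- if (trait_regression) {
    "delta[i] <- omega + psi * mig[i] + eta * blat[i]"
  } else {
    "delta[i] <- omega"
  }
  trait_priors <- if (trait_regression) "
  psi ~ dnorm(0, 1)
  eta ~ dnorm(0, 1)" else ""
  sprintf("
model {
  for (j in 1:N) {
    y[j] ~ dgamma(shp[sp[j]], shp[sp[j]] / exp(lp[j]))
    lp[j] <- alpha[yr[j], sp[j]] + beta[yr[j], sp[j]] * X[j]%s%s
  }
  for (i in 1:NS) {
    shp[i] ~ dnorm(mu_shp, tau_shp) T(0.001,)
    gam[i] ~ dnorm(mu_gamma, tau_gamma)
    %s
    mu_beta[i] ~ dnorm(delta[i], tau_delta)%s
    for (t in 1:NY) {
      alpha[t, i] ~ dnorm(gam[i], tau_alpha)
      beta[t, i] ~ dnorm(mu_beta[i], tau_beta)
    }
  }
  omega ~ dnorm(0, 1)%s
  mu_gamma ~ dnorm(0, 0.01)
  mu_shp ~ dnorm(0, 0.04) T(0,)%s
  sd_shp ~ dnorm(0, 1) T(0,); tau_shp <- pow(sd_shp, -2)
  sd_gamma ~ dnorm(0, 1) T(0,); tau_gamma <- pow(sd_gamma, -2)
  sd_delta ~ dnorm(0, 1) T(0,); tau_delta <- pow(sd_delta, -2)
  sd_alpha ~ dnorm(0, 1) T(0,); tau_alpha <- pow(sd_alpha, -2)
  sd_beta ~ dnorm(0, 1) T(0,); tau_beta <- pow(sd_beta, -2)
}", lp_age, age_block, delta, age_sp, trait_priors, age_priors)
}

jags_model_interaction <- function() {
  "
model {
  for (j in 1:N) {
    y[j] ~ dgamma(shp[sp[j]], shp[sp[j]] / exp(lp[j]))
    lp[j] <- alpha[yr[j], sp[j]] + beta[sp[j]] * X1[j] + theta[sp[j]] * X2[j] +
             omega_i[sp[j]] * X1[j] * X2[j]
  }
  for (i in 1:NS) {
    shp[i] ~ dnorm(mu_shp, tau_shp) T(0.001,)
    beta[i] ~ dnorm(mu_beta, tau_beta)
    theta[i] ~ dnorm(mu_theta, tau_theta)
    omega_i[i] ~ dnorm(mu_omega, tau_omega)
    mu_alpha[i] ~ dnorm(gamma0, tau_mu_alpha)
    for (t in 1:NY) {
      alpha[t, i] ~ dnorm(mu_alpha[i], tau_alpha)
    }
  }
  mu_beta ~ dnorm(0, 1)
  mu_theta ~ dnorm(0, 1)
  mu_omega ~ dnorm(0, 1)
  gamma0 ~ dnorm(0, 0.01)
  mu_shp ~ dnorm(0, 0.04) T(0,)
  sd_shp ~ dnorm(0, 1) T(0,); tau_shp <- pow(sd_shp, -2)
  sd_beta ~ dnorm(0, 1) T(0,); tau_beta <- pow(sd_beta, -2)
  sd_theta ~ dnorm(0, 1) T(0,); tau_theta <- pow(sd_theta, -2)
  sd_omega ~ dnorm(0, 1) T(0,); tau_omega <- pow(sd_omega, -2)
  sd_mu_alpha ~ dnorm(0, 1) T(0,); tau_mu_alpha <- pow(sd_mu_alpha, -2)
  sd_alpha ~ dnorm(0, 1) T(0,); tau_alpha <- pow(sd_alpha, -2)
}"
}

top_level_params <- function(spec) {
  if (spec$form == "single_driver") {
    c("omega",
      if (spec$trait_regression) c("psi", "eta"),
      if (spec$include_age_terms) c("mu_lambda", "mu_nu"),
      "mu_gamma")
  } else {
    c("mu_beta", "mu_theta", "mu_omega", "gamma0")
  }
}

#' Fit a hierarchical vagrancy model
#'
#' Compiles and samples the JAGS model implied by `spec`. Unknown-age rows
#' (when imputed) contribute through a latent per-record Bernoulli age with
#' species-level prevalence `pi_i ~ Beta(2, 2)`. Slope-level means carry
#' Normal(0, 1) priors on the standardized scale, hierarchical SDs
#' half-Normal(0, 1), intercept means Normal(0, 10), and the shape mean
#' half-Normal(0, 5). Convergence is assessed with split-chain R-hat
#' (threshold 1.05) and effective sample size (threshold 100) on the
#' top-level parameters; a failing fit is returned with `converged = FALSE`
#' and a warning, not discarded.
#'
#' @param spec a [model_spec()].
#' @param inputs a [build_inputs()] result.
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return a `vgm_fit`: list with `draws` (matrix, pooled chains x
#'   parameters), `spec`, `species_codes`, `years`, `rhat`, `ess`,
#'   `converged`.
#' @export
fit_vagrancy_model <- function(spec, inputs, quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(inputs, "model_inputs"))
  single <- spec$form == "single_driver"
  data <- list(
    y = inputs$y, sp = inputs$sp, yr = inputs$yr,
    N = length(inputs$y), NS = inputs$n_species, NY = inputs$n_years
  )
  if (single) {
    data$X <- inputs$X
    if (spec$include_age_terms) data$age <- inputs$age
    if (spec$trait_regression) {
      data$mig <- inputs$mig_z
      data$blat <- inputs$blat_z
    }
    model_str <- jags_model_single(spec$include_age_terms,
                                   spec$trait_regression)
  } else {
    data$X1 <- inputs$X1
    data$X2 <- inputs$X2
    model_str <- jags_model_interaction()
  }
  ly <- mean(log(inputs$y))
  inits <- lapply(seq_len(spec$chains), function(ch) {
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (spec$seed * 1000L + ch) %% 2147483629L,
      mu_shp = 2, shp = rep(2, inputs$n_species),
      alpha = matrix(ly, inputs$n_years, inputs$n_species)
    )
    if (single) {
      ini$mu_gamma <- ly
      ini$gam <- rep(ly, inputs$n_species)
      ini$omega <- 0
      ini$mu_beta <- rep(0, inputs$n_species)
      ini$beta <- matrix(0, inputs$n_years, inputs$n_species)
      if (spec$trait_regression) ini[c("psi", "eta")] <- list(0, 0)
      if (spec$include_age_terms) {
        ini$mu_lambda <- 0
        ini$mu_nu <- 0
        ini$lambda <- rep(0, inputs$n_species)
        ini$nu <- rep(0, inputs$n_species)
      }
    } else {
      ini$gamma0 <- ly
      ini$mu_alpha <- rep(ly, inputs$n_species)
      ini[c("mu_beta", "mu_theta", "mu_omega")] <- list(0, 0, 0)
      ini$beta <- rep(0, inputs$n_species)
      ini$theta <- rep(0, inputs$n_species)
      ini$omega_i <- rep(0, inputs$n_species)
    }
    ini
  })
  monitors <- if (single) {
    c(top_level_params(spec), "mu_shp", "mu_beta", "gam", "shp",
      "alpha", "beta", "sd_alpha", "sd_beta", "sd_delta", "sd_gamma",
      if (spec$include_age_terms) c("lambda", "nu", "prev"))
  } else {
    c(top_level_params(spec), "mu_shp", "beta", "theta", "omega_i",
      "mu_alpha", "shp", "alpha", "sd_alpha", "sd_beta", "sd_theta",
      "sd_omega")
  }
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            inits = inits, n.chains = spec$chains,
                            n.adapt = spec$n_adapt, quiet = quiet)
    if (spec$n_burn > 0) {
      stats::update(jm, n.iter = spec$n_burn, progress.bar = "none")
    }
    rjags::coda.samples(jm, unique(monitors), n.iter = spec$n_iter,
                        thin = spec$thin, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  top <- intersect(top_level_params(spec), colnames(samples[[1]]))
  rhat <- rep(NA_real_, length(top))
  names(rhat) <- top
  if (spec$chains >= 2) {
    gd <- tryCatch(
      coda::gelman.diag(samples[, top, drop = FALSE], autoburnin = FALSE,
                        multivariate = FALSE),
      error = function(e) NULL
    )
    if (!is.null(gd)) rhat[rownames(gd$psrf)] <- gd$psrf[, 1]
  }
  ess <- vapply(top, function(p) {
    sum(vapply(samples, function(ch) {
      unname(coda::effectiveSize(ch[, p]))
    }, numeric(1)))
  }, numeric(1))
  converged <- all(is.na(rhat) | rhat <= 1.05) && all(ess >= 100)
  if (!converged) {
    warning("convergence diagnostics exceeded thresholds (R-hat > 1.05 or ",
            "ESS < 100) for: ",
            paste(top[(!is.na(rhat) & rhat > 1.05) | ess < 100],
                  collapse = ", "))
  }
  structure(list(
    draws = as.matrix(samples), spec = spec,
    species_codes = inputs$species_codes, years = inputs$years,
    n_chains = spec$chains, n_iter_kept = spec$n_iter %/% spec$thin,
    rhat = rhat, ess = ess, converged = converged
  ), class = "vgm_fit")
}

#' @export
print.vgm_fit <- function(x, ...) {
  cat(sprintf(
    "vgm hierarchical gamma fit (%s, %s): %d species, %d years\n",
    x$spec$form, x$spec$season, length(x$species_codes), length(x$years)
  ))
  cat(sprintf("%d chains x %d kept iterations; converged: %s\n",
              x$n_chains, x$n_iter_kept, x$converged))
  for (p in names(x$rhat)) {
    s <- summarize_draws(x, p)
    cat(sprintf(
      "  %-10s median %8.4f  95%% CrI (%8.4f, %8.4f)  p(%s0) = %.2f  Rhat %.3f\n",
      p, s$median, s$lower, s$upper, if (s$median > 0) ">" else "<",
      s$tail_prob, x$rhat[p]
    ))
  }
  invisible(x)
}

#' Summarize a posterior parameter
#'
#' Median, equal-tailed 95% credible interval and the tail probability —
#' the share of draws above zero when the median is positive, below zero
#' otherwise (the convention used for reporting directional evidence).
#'
#' @param fit a `vgm_fit` (or a draws matrix with named columns).
#' @param parameter parameter name, e.g. `"omega"` or `"mu_beta[3]"`. A bare
#'   family name matching vector-valued columns returns one row per element.
#' @return one-row data frame (`parameter`, `median`, `lower`, `upper`,
#'   `tail_prob`), or several rows for a family.
#' @export
summarize_draws <- function(fit, parameter) {
  draws <- if (inherits(fit, "vgm_fit")) fit$draws else fit
  cols <- colnames(draws)
  if (parameter %in% cols) {
    hits <- parameter
  } else {
    hits <- cols[startsWith(cols, paste0(parameter, "["))]
    if (length(hits) == 0) {
      fams <- unique(sub("\\[.*$", "", cols))
      stop("unknown parameter '", parameter, "'; available: ",
           paste(fams, collapse = ", "))
    }
  }
  out <- do.call(rbind, lapply(hits, function(h) {
    d <- draws[, h]
    q <- unname(stats::quantile(d, c(0.5, 0.025, 0.975)))
    tail_prob <- if (q[1] > 0) mean(d > 0) else mean(d < 0)
    data.frame(parameter = h, median = q[1], lower = q[2], upper = q[3],
               tail_prob = tail_prob, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Predicted percent change in median vagrancy per covariate change
#'
#' Under the log link, an effect of `effect_per_sd` per SD implies a
#' multiplicative change of `exp(effect_per_sd * delta_sd)` in the predicted
#' median vagrancy index for a `delta_sd`-SD increase of the covariate;
#' returned as a percentage.
#'
#' @param effect_per_sd effect on the log scale per SD of the covariate.
#' @param delta_sd covariate change in SD units.
#' @return percent change.
#' @examples
#' predicted_change_percent(0.109, 2) # ~24% for the typical-species effect
#' @export
predicted_change_percent <- function(effect_per_sd, delta_sd) {
  stopifnot(is.finite(effect_per_sd), is.finite(delta_sd))
  100 * (exp(effect_per_sd * delta_sd) - 1)
}

#' Species-level sensitivities from a fit
#'
#' Posterior medians of the species-level slope: `mu_beta[i]` for the
#' single-driver form; `beta[i]`, `theta[i]` or `omega_i[i]` for the
#' interaction form.
#'
#' @param fit a `vgm_fit`.
#' @param parameter slope family (default the driver slope of the fit form).
#' @return data frame `species_code`, `sensitivity`.
#' @export
species_sensitivity <- function(fit, parameter = NULL) {
  if (is.null(parameter)) {
    parameter <- if (fit$spec$form == "single_driver") "mu_beta" else "theta"
  }
  s <- summarize_draws(fit, parameter)
  i <- as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", s$parameter))
  data.frame(species_code = fit$species_codes[i], sensitivity = s$median,
             stringsAsFactors = FALSE)
}

#' Bayesian R-squared of the interaction model, per species
#'
#' For each posterior draw and species, the covariate-explained part of each
#' record is `g_j = beta_i X1_j + theta_i X2_j + omega_i X1_j X2_j` and the
#' residual is `y_j - g_j`; the variance ratio `V(g) / (V(g) + V(resid))` is
#' the share of total variance attributed to the covariates. Reported as the
#' posterior median per species plus the cross-species median.
#'
#' @param fit a `vgm_fit` of the interaction form (or a draws matrix with
#'   `beta[i]`, `theta[i]`, `omega_i[i]` columns).
#' @param inputs the [build_inputs()] result the model was fit to.
#' @param max_draws cap on posterior draws used (default 400).
#' @return list with `per_species` (data frame `species_code`, `r2`) and
#'   `overall` (median of the species-level medians).
#' @export
bayesian_r2 <- function(fit, inputs, max_draws = 400) {
  draws <- if (inherits(fit, "vgm_fit")) fit$draws else fit
  ns <- inputs$n_species
  need <- c(sprintf("beta[%d]", seq_len(ns)), sprintf("theta[%d]", seq_len(ns)),
            sprintf("omega_i[%d]", seq_len(ns)))
  if (!all(need %in% colnames(draws))) {
    stop("bayesian_r2 needs interaction-form draws (beta, theta, omega_i)")
  }
  take <- round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws))))
  b <- draws[take, sprintf("beta[%d]", seq_len(ns)), drop = FALSE]
  th <- draws[take, sprintf("theta[%d]", seq_len(ns)), drop = FALSE]
  om <- draws[take, sprintf("omega_i[%d]", seq_len(ns)), drop = FALSE]
  r2 <- matrix(NA_real_, length(take), ns)
  for (i in seq_len(ns)) {
    rows <- inputs$sp == i
    x1 <- inputs$X1[rows]
    x2 <- inputs$X2[rows]
    y <- inputs$y[rows]
    for (d in seq_along(take)) {
      g <- b[d, i] * x1 + th[d, i] * x2 + om[d, i] * x1 * x2
      vg <- stats::var(g)
      ve <- stats::var(y - g)
      r2[d, i] <- if (vg + ve == 0) NA_real_ else vg / (vg + ve)
    }
  }
  per_species <- data.frame(
    species_code = inputs$species_codes,
    r2 = apply(r2, 2, stats::median, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  list(per_species = per_species,
       overall = stats::median(per_species$r2, na.rm = TRUE))
}

#' Posterior predictive check per species
#'
#' Simulates replicated vagrancy data from the fitted gamma likelihood for a
#' subsample of posterior draws and compares a per-species statistic between
#' replicated and observed data. The tail probability is the share of
#' replicates whose statistic exceeds the observed one (ties split); values
#' near 0 or 1 flag misfit, values near 0.5 are ideal.
#'
#' @param fit a `vgm_fit`.
#' @param inputs the matching [build_inputs()] result.
#' @param statistic `"mean"`, `"sd"`, `"max"`, or `"prop_above_q90"` (share
#'   of values above the species' observed 90th percentile).
#' @param n_draws posterior draws to use (default 200).
#' @return data frame `species_code`, `observed`, `ppc_tail_prob`.
#' @export
posterior_predictive_check <- function(fit, inputs,
                                       statistic = c("mean", "sd", "max",
                                                     "prop_above_q90"),
                                       n_draws = 200) {
  statistic <- match.arg(statistic)
  draws <- fit$draws
  take <- round(seq(1, nrow(draws), length.out = min(n_draws, nrow(draws))))
  ns <- inputs$n_species
  q90 <- vapply(seq_len(ns), function(i) {
    unname(stats::quantile(inputs$y[inputs$sp == i], 0.9))
  }, numeric(1))
  stat_fun <- switch(statistic,
    mean = function(v, i) mean(v),
    sd = function(v, i) stats::sd(v),
    max = function(v, i) max(v),
    prop_above_q90 = function(v, i) mean(v > q90[i])
  )
  obs <- vapply(seq_len(ns), function(i) {
    stat_fun(inputs$y[inputs$sp == i], i)
  }, numeric(1))
  exceed <- matrix(0, length(take), ns)
  for (d in seq_along(take)) {
    lp <- linear_predictor(fit, inputs, draws[take[d], ])
    shp <- draws[take[d], sprintf("shp[%d]", inputs$sp)]
    yrep <- stats::rgamma(length(lp), shape = shp, rate = shp / exp(lp))
    for (i in seq_len(ns)) {
      s <- stat_fun(yrep[inputs$sp == i], i)
      exceed[d, i] <- (s > obs[i]) + 0.5 * (s == obs[i])
    }
  }
  data.frame(
    species_code = inputs$species_codes,
    observed = obs,
    ppc_tail_prob = colMeans(exceed),
    stringsAsFactors = FALSE
  )
}

# Reconstruct the linear predictor for one posterior draw (named vector).
# Unknown ages are imputed from the species prevalence for PPC purposes.
linear_predictor <- function(fit, inputs, draw) {
  sp <- inputs$sp
  yr <- inputs$yr
  if (fit$spec$form == "single_driver") {
    lp <- draw[sprintf("alpha[%d,%d]", yr, sp)] +
      draw[sprintf("beta[%d,%d]", yr, sp)] * inputs$X
    if (fit$spec$include_age_terms) {
      age <- inputs$age
      if (anyNA(age)) {
        pi_i <- draw[sprintf("prev[%d]", sp[is.na(age)])]
        age[is.na(age)] <- stats::rbinom(sum(is.na(inputs$age)), 1, pi_i)
      }
      lp <- lp + draw[sprintf("lambda[%d]", sp)] * age +
        draw[sprintf("nu[%d]", sp)] * age * inputs$X
    }
    unname(lp)
  } else {
    unname(draw[sprintf("alpha[%d,%d]", yr, sp)] +
      draw[sprintf("beta[%d]", sp)] * inputs$X1 +
      draw[sprintf("theta[%d]", sp)] * inputs$X2 +
      draw[sprintf("omega_i[%d]", sp)] * inputs$X1 * inputs$X2)
  }
}
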