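# Synthetic worlds with known ground truth: weekly abundance surfaces that
# drift between breeding and non-breeding centres, AR(1) geomagnetic/solar
# index series around a solar-cycle sinusoid, banding records drawn from the
# generative twin of the hierarchical gamma model, species traits, and
# phylogenies. Everything downstream of real data acquisition can be
# exercised against these with controllable effect sizes.

#' Configuration of a synthetic world
#'
#' @param n_species number of species.
#' @param n_years number of study years.
#' @param start_year first calendar year.
#' @param lon_range,lat_range grid extent, decimal degrees.
#' @param cell_deg grid cell size in degrees (default 1).
#' @param bandwidth_deg abundance kernel bandwidth in degrees (default 3);
#'   each weekly surface is a truncated Gaussian bump of this width.
#' @param drift `"linear"` (centroid interpolates between breeding and
#'   non-breeding centres over the migration weeks) or `"constant"`
#'   (stationary at the breeding centre).
#' @param ar1 lag-1 autocorrelation of the daily index noise, in \[0, 1).
#' @param solar_cycle_days period of the sinusoidal baseline (default 4015,
#'   approximately the 11-year solar cycle).
#' @param cycle_amp relative amplitude of the sinusoidal baseline (1 =
#'   default amplitudes; 0 = flat baseline, indices reduce to AR(1) noise).
#' @param fall_weeks,spring_weeks migration weeks of year.
#' @param breeding_weeks,nonbreeding_weeks stationary-season weeks used for
#'   seasonal centroids.
#' @param seed integer; the single source of randomness for the world.
#' @return a `world_config` list.
#' @export
world_config <- function(n_species = 8, n_years = 4, start_year = 2000,
                         lon_range = c(-110, -70), lat_range = c(22, 56),
                         cell_deg = 1, bandwidth_deg = 3,
                         drift = c("linear", "constant"),
                         ar1 = 0.8, solar_cycle_days = 4015, cycle_amp = 1,
                         fall_weeks = 32:45, spring_weeks = 14:23,
                         breeding_weeks = 25:28, nonbreeding_weeks = 1:4,
                         seed = 1) {
  drift <- match.arg(drift)
  stopifnot(
    n_species >= 1, n_years >= 1, bandwidth_deg > 0,
    ar1 >= 0, ar1 < 1, cell_deg > 0,
    diff(lon_range) > 0, diff(lat_range) > 0
  )
  if (diff(lon_range) <= cell_deg && diff(lat_range) <= cell_deg) {
    stop("degenerate grid: extent smaller than one cell")
  }
  structure(as.list(environment()), class = "world_config")
}

#' Ground-truth generative parameters
#'
#' The generative twin of the inferential model: a global covariate effect
#' per SD (`omega`), trait moderation of species sensitivity (`psi` on
#' standardized migration length, `eta` on standardized breeding latitude),
#' a young-bird intercept offset (`lambda`) and young-bird sensitivity
#' offset (`nu`), per-species gamma shapes, the standard deviations of each
#' hierarchical level, and the probability that a record's age is unrecorded.
#'
#' @param omega global covariate effect per SD (default 0.11).
#' @param psi,eta trait moderation effects per SD (defaults 0.04, 0).
#' @param lambda young-bird intercept offset (default 0.05).
#' @param nu young-bird sensitivity offset (default 0).
#' @param mu_gamma mean log vagrancy across species (default 5, i.e.
#'   exp(5) ~ 148 km typical index).
#' @param sigma_gamma,sigma_alpha,sigma_delta,sigma_beta,sigma_lambda,sigma_nu
#'   hierarchical standard deviations.
#' @param shape_range per-species gamma shapes are drawn uniformly from this
#'   range (must be positive).
#' @param age_missing_prob probability an age is masked to unknown, in
#'   \[0, 1\].
#' @return a `truth_params` list.
#' @export
truth_params <- function(omega = 0.11, psi = 0.04, eta = 0,
                         lambda = 0.05, nu = 0,
                         mu_gamma = 5,
                         sigma_gamma = 0.3, sigma_alpha = 0.1,
                         sigma_delta = 0.05, sigma_beta = 0.05,
                         sigma_lambda = 0.04, sigma_nu = 0.02,
                         shape_range = c(1.5, 4),
                         age_missing_prob = 0.3) {
  stopifnot(
    all(shape_range > 0), age_missing_prob >= 0, age_missing_prob <= 1,
    sigma_gamma >= 0, sigma_alpha >= 0, sigma_delta >= 0, sigma_beta >= 0
  )
  structure(as.list(environment()), class = "truth_params")
}

# Weekly centroid of one species: linear interpolation breeding ->
# non-breeding across the fall weeks (reverse in spring), stationary in the
# stationary seasons and under a constant drift schedule.
week_centroid <- function(config, breeding, nonbreeding, week) {
  if (config$drift == "constant") return(breeding)
  fw <- config$fall_weeks
  sw <- config$spring_weeks
  frac <- if (week %in% fw) {
    (match(week, fw) - 1) / max(1, length(fw) - 1)
  } else if (week %in% sw) {
    1 - (match(week, sw) - 1) / max(1, length(sw) - 1)
  } else if (week %in% config$nonbreeding_weeks) 1 else 0
  breeding + frac * (nonbreeding - breeding)
}

make_surface <- function(config, species, week, centre) {
  lon <- seq(config$lon_range[1] + config$cell_deg / 2, config$lon_range[2],
             by = config$cell_deg)
  lat <- seq(config$lat_range[1] + config$cell_deg / 2, config$lat_range[2],
             by = config$cell_deg)
  g <- expand.grid(lon = lon, lat = lat)
  d2 <- (g$lon - centre[1])^2 + (g$lat - centre[2])^2
  bw <- config$bandwidth_deg
  mask <- d2 <= (4 * bw)^2 # modeled range: within 4 bandwidths
  ab <- ifelse(mask, exp(-d2 / (2 * bw^2)), 0)
  if (sum(ab) == 0) stop("abundance bump fell entirely off the grid")
  ab <- ab / sum(ab)
  as_surface(data.frame(
    species_code = species, week = week, lon = g$lon, lat = g$lat,
    abundance = ab, mask = mask
  ))
}

simulate_index <- function(dates, base, amp, sd_noise, ar1, period,
                           phase = 0) {
  n <- length(dates)
  t <- seq_len(n)
  e <- numeric(n)
  z <- stats::rnorm(n)
  e[1] <- z[1] * sd_noise
  if (n > 1) {
    for (i in 2:n) e[i] <- ar1 * e[i - 1] + sqrt(1 - ar1^2) * sd_noise * z[i]
  }
  v <- pmax(0, base + amp * sin(2 * pi * t / period + phase) + e)
  validate_index(data.frame(date = dates, value = v), name = "index",
                 context = "synthetic index")
}

# Month-day bounds of a week-of-year range, generous by up to a day so that
# both leap and non-leap years fall inside the window.
week_start_md <- function(week) {
  strftime(as.Date((week - 1) * 7, origin = "2000-01-01"), "%m-%d")
}
week_end_md <- function(week) {
  strftime(as.Date(week * 7 - 1, origin = "2001-01-01"), "%m-%d")
}

#' Generate a synthetic world
#'
#' Builds weekly abundance surfaces for every species over the migration and
#' stationary seasons (truncated Gaussian bumps whose centroids interpolate
#' between breeding and non-breeding centres; each surface sums to one over
#' unmasked cells), two correlated daily index series (AR(1) noise around a
#' solar-cycle sinusoid, floored at zero: physical disturbance indices are
#' nonnegative), a species-trait table, and per-species season windows.
#'
#' @param config a [world_config()].
#' @return list with `config`, `surfaces` (named `"<sp>_w<week>"`),
#'   `geomag`, `solar` (daily index series), `traits`, and `centers`.
#' @export
gen_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr_seed(config$seed, {
    n <- config$n_species
    sp <- sprintf("SP%02d", seq_len(n))
    # breeding centres in the northern half, non-breeding in the southern
    lon_mid <- mean(config$lon_range)
    lon_span <- diff(config$lon_range)
    breeding <- cbind(
      lon = stats::runif(n, lon_mid - lon_span / 4, lon_mid + lon_span / 4),
      lat = stats::runif(n, config$lat_range[2] - 12, config$lat_range[2] - 6)
    )
    nonbreeding <- cbind(
      lon = breeding[, "lon"] + stats::runif(n, -5, 5),
      lat = stats::runif(n, config$lat_range[1] + 6, config$lat_range[1] + 12)
    )
    weeks <- sort(unique(c(config$fall_weeks, config$spring_weeks,
                           config$breeding_weeks, config$nonbreeding_weeks)))
    surfaces <- list()
    for (i in seq_len(n)) {
      for (w in weeks) {
        centre <- week_centroid(config, breeding[i, ], nonbreeding[i, ], w)
        surfaces[[sprintf("%s_w%02d", sp[i], w)]] <-
          make_surface(config, sp[i], w, centre)
      }
    }
    dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)) - 30,
                 as.Date(sprintf("%d-12-31",
                                 config$start_year + config$n_years - 1)),
                 by = "day")
    # shared sinusoid phase induces a positive correlation between the two
    # series, as observed between real geomagnetic and sunspot indices
    geomag <- simulate_index(dates, base = 13, amp = 4 * config$cycle_amp,
                             sd_noise = 5, ar1 = config$ar1,
                             period = config$solar_cycle_days)
    solar <- simulate_index(dates, base = 56, amp = 35 * config$cycle_amp,
                            sd_noise = 14, ar1 = config$ar1,
                            period = config$solar_cycle_days)
    attr(geomag, "name") <- "geomagnetic"
    attr(solar, "name") <- "solar"
    traits <- data.frame(
      species_code = sp,
      migration_length_km = haversine_km(
        breeding[, "lon"], breeding[, "lat"],
        nonbreeding[, "lon"], nonbreeding[, "lat"]
      ),
      breeding_latitude_deg = breeding[, "lat"],
      wintering_latitude_deg = nonbreeding[, "lat"],
      diel = rep_len(c("nocturnal", "diurnal"), n),
      fall_start = week_start_md(min(config$fall_weeks)),
      fall_end = week_end_md(max(config$fall_weeks)),
      spring_start = week_start_md(min(config$spring_weeks)),
      spring_end = week_end_md(max(config$spring_weeks)),
      stringsAsFactors = FALSE
    )
    traits$exclusion_windows <- rep(list(
      data.frame(start = as.Date(character()), end = as.Date(character()))
    ), n)
    list(config = config, surfaces = surfaces, geomag = geomag,
         solar = solar, traits = traits,
         centers = list(breeding = breeding, nonbreeding = nonbreeding))
  })
}

#' Generate banding records from the generative model
#'
#' In `"model_level"` mode each record's vagrancy index is drawn directly
#' from the gamma law `y ~ gamma(shp_i, shp_i / exp(lp))`, with the linear
#' predictor assembled from the record date's standardized 21-day rolling
#' covariate and the hierarchical species/year effects; this makes the
#' statistical machinery testable against exact ground truth. In `"spatial"`
#' mode the record is placed on the landscape instead: a base location drawn
#' from the species-week surface, displaced by an exponential distance with
#' mean `exp(lp)` km in a uniform direction, so the geometry pipeline (point
#' clouds, nearest neighbours) is exercised end to end. Ages are Bernoulli
#' per species and masked to unknown with probability `age_missing_prob`.
#'
#' @param world a [gen_world()] result.
#' @param truth a [truth_params()].
#' @param n_per_species_year records per species per year (> 0).
#' @param mode `"model_level"` or `"spatial"`.
#' @param season `"fall"` or `"spring"`.
#' @param driver `"geomag"` or `"solar"`: which index drives the effect.
#' @param seed integer seed.
#' @return banding-record data frame; in model_level mode with a
#'   `vagrancy_km` column, and in both modes with attribute `"truth"`
#'   holding the realized hierarchical parameters, true ages, linear
#'   predictors and the covariate standardization used.
#' @export
gen_banding_records <- function(world, truth, n_per_species_year = 50,
                                mode = c("model_level", "spatial"),
                                season = c("fall", "spring"),
                                driver = c("geomag", "solar"), seed = 1) {
  mode <- match.arg(mode)
  season <- match.arg(season)
  driver <- match.arg(driver)
  stopifnot(inherits(truth, "truth_params"))
  if (n_per_species_year <= 0) stop("n_per_species_year must be positive")
  config <- world$config
  sp <- world$traits$species_code
  n_sp <- length(sp)
  n_yr <- config$n_years
  weeks <- if (season == "fall") config$fall_weeks else config$spring_weeks
  index <- if (driver == "geomag") world$geomag else world$solar
  roll <- rolling_mean_21(index)

  withr_seed(seed, {
    # realized hierarchical parameters
    mig_z <- standardize(world$traits$migration_length_km)$z
    blat_z <- standardize(world$traits$breeding_latitude_deg)$z
    shp <- stats::runif(n_sp, truth$shape_range[1], truth$shape_range[2])
    gamma_i <- stats::rnorm(n_sp, truth$mu_gamma, truth$sigma_gamma)
    delta_i <- truth$omega + truth$psi * mig_z + truth$eta * blat_z
    mu_beta <- stats::rnorm(n_sp, delta_i, truth$sigma_delta)
    lambda_i <- stats::rnorm(n_sp, truth$lambda, truth$sigma_lambda)
    nu_i <- stats::rnorm(n_sp, truth$nu, truth$sigma_nu)
    pi_i <- stats::runif(n_sp, 0.35, 0.65)
    alpha <- matrix(stats::rnorm(n_yr * n_sp, rep(gamma_i, each = n_yr),
                                 truth$sigma_alpha), n_yr, n_sp)
    beta <- matrix(stats::rnorm(n_yr * n_sp, rep(mu_beta, each = n_yr),
                                truth$sigma_beta), n_yr, n_sp)

    # record dates: uniform over the season's weeks, per species x year
    rows <- expand.grid(rep = seq_len(n_per_species_year),
                        year = seq_len(n_yr), species = seq_len(n_sp))
    n_rec <- nrow(rows)
    year0 <- config$start_year - 1
    doy <- sample((min(weeks) - 1) * 7 + seq_len(length(weeks) * 7),
                  n_rec, replace = TRUE)
    date <- as.Date(doy,
                    origin = sprintf("%d-12-31", year0 + rows$year - 1))
    x_raw <- roll$rolling_mean_21[match(date, roll$date)]
    zx <- standardize(x_raw)
    age_true <- stats::rbinom(n_rec, 1, pi_i[rows$species])
    lp <- alpha[cbind(rows$year, rows$species)] +
      beta[cbind(rows$year, rows$species)] * zx$z +
      lambda_i[rows$species] * age_true +
      nu_i[rows$species] * age_true * zx$z
    y <- stats::rgamma(n_rec, shape = shp[rows$species],
                       rate = shp[rows$species] / exp(lp))

    wk <- week_of_year(date)
    loc <- matrix(NA_real_, n_rec, 2)
    for (g in unique(paste(rows$species, wk))) {
      idx <- which(paste(rows$species, wk) == g)
      key <- sprintf("%s_w%02d", sp[rows$species[idx[1]]], wk[idx[1]])
      surf <- world$surfaces[[key]]
      if (is.null(surf)) stop("no surface for group ", key)
      pts <- sample_abundance_points(surf, length(idx),
                                     seed = group_seed(seed, g))
      loc[idx, ] <- as.matrix(pts)
    }
    if (mode == "spatial") {
      # displace by an exponential distance with mean exp(lp), uniform bearing
      d_km <- stats::rexp(n_rec, rate = 1 / exp(lp))
      theta <- stats::runif(n_rec, 0, 2 * pi)
      loc[, 2] <- loc[, 2] + d_km * cos(theta) / 111.195
      loc[, 1] <- loc[, 1] + d_km * sin(theta) /
        (111.195 * pmax(0.2, cos(loc[, 2] * pi / 180)))
      loc[, 1] <- pmax(-180, pmin(180, loc[, 1]))
      loc[, 2] <- pmax(-90, pmin(90, loc[, 2]))
    }

    age_class <- ifelse(age_true == 1, "young", "adult")
    hidden <- stats::runif(n_rec) < truth$age_missing_prob
    age_class[hidden] <- "unknown"

    records <- data.frame(
      record_id = sprintf("R%06d", seq_len(n_rec)),
      species_code = sp[rows$species],
      date = date,
      lon = loc[, 1], lat = loc[, 2],
      precision_km = 0,
      age_class = age_class,
      record_type = "banding",
      banding_code = 3L,
      stringsAsFactors = FALSE
    )
    if (mode == "model_level") records$vagrancy_km <- y
    attr(records, "truth") <- list(
      shp = shp, gamma_i = gamma_i, mu_beta = mu_beta, delta_i = delta_i,
      lambda_i = lambda_i, nu_i = nu_i, pi_i = pi_i,
      alpha = alpha, beta = beta, lp = lp, y = y, age_true = age_true,
      x_mean = zx$mean, x_sd = zx$sd, mig_z = mig_z, blat_z = blat_z,
      truth = truth
    )
    records
  })
}

#' Generate a Yule phylogeny with trait values
#'
#' Topology is a pure-birth (Yule) tree; tip values are either a Brownian
#' motion realization along the branches (phylogenetic signal present,
#' Blomberg's K near 1) or i.i.d. normal white noise (no signal, K well
#' below 1).
#'
#' @param n_species at least 4 (Blomberg's K is not meaningful below that).
#' @param model `"brownian"` or `"white_noise"`.
#' @param seed integer seed.
#' @return list with `tree` (an [ape::phylo], tip labels `SP01...`) and
#'   `values` (named numeric per tip).
#' @export
gen_phylogeny_traits <- function(n_species, model = c("brownian", "white_noise"),
                                 seed = 1) {
  model <- match.arg(model)
  if (n_species < 4) stop("need at least 4 species for a meaningful tree")
  withr_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("SP%02d", seq_len(n_species))
    values <- if (model == "brownian") {
      ape::rTraitCont(tree, model = "BM", sigma = 1)
    } else {
      stats::setNames(stats::rnorm(n_species), tree$tip.label)
    }
    list(tree = tree, values = values)
  })
}

#' Write a synthetic world and its records to a fixture bundle
#'
#' Layout: `records.csv`, `ap_index.csv`, `sunspots.csv`, `traits.csv`,
#' `surfaces/<species>_w<week>.csv`, optional `tree.nwk` and `truth.json`.
#' Everything round-trips losslessly through the `read_*` functions.
#'
#' @param world a [gen_world()] result.
#' @param records banding-record data frame.
#' @param path directory to create.
#' @param tree optional [ape::phylo].
#' @param truth optional [truth_params()] (written as JSON).
#' @return `path`, invisibly.
#' @export
write_fixture_bundle <- function(world, records, path, tree = NULL,
                                 truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "surfaces"), showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create fixture directory ", path)
  write_records(records, file.path(path, "records.csv"))
  write_index(world$geomag, file.path(path, "ap_index.csv"))
  write_index(world$solar, file.path(path, "sunspots.csv"))
  write_traits(world$traits, file.path(path, "traits.csv"))
  for (key in names(world$surfaces)) {
    write_surface(world$surfaces[[key]],
                  file.path(path, "surfaces", paste0(key, ".csv")))
  }
  if (!is.null(tree)) ape::write.tree(tree, file.path(path, "tree.nwk"))
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param path bundle directory.
#' @return list with `records`, `geomag`, `solar`, `traits`, `surfaces`,
#'   and (when present) `tree` and `truth`.
#' @export
read_fixture_bundle <- function(path) {
  surfaces <- list()
  for (f in list.files(file.path(path, "surfaces"), full.names = TRUE)) {
    s <- read_surface(f)
    surfaces[[sprintf("%s_w%02d", attr(s, "species_code"), attr(s, "week"))]] <- s
  }
  out <- list(
    records = read_records(file.path(path, "records.csv")),
    geomag = read_index(file.path(path, "ap_index.csv"), "geomagnetic"),
    solar = read_index(file.path(path, "sunspots.csv"), "solar"),
    traits = read_traits(file.path(path, "traits.csv")),
    surfaces = surfaces
  )
  if (file.exists(file.path(path, "tree.nwk"))) {
    out$tree <- read_tree(file.path(path, "tree.nwk"))
  }
  if (file.exists(file.path(path, "truth.json"))) {
    out$truth <- jsonlite::read_json(file.path(path, "truth.json"),
                                     simplifyVector = TRUE)
  }
  out
}
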