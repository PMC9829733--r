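# Model covariates: 21-day rolling geomagnetic/solar indices joined to
# records by date, z-standardization, and species traits (seasonal abundance
# centroids, migration length).

#' 21-day trailing rolling mean of a daily index series
#'
#' The value at day t is the mean of the raw values over days t-20..t
#' inclusive (the capture day and the 20 days before it — the latency window
#' between a disturbance and the capture of an affected bird). The first 20
#' days of the series carry `NA`.
#'
#' @param series an index data frame (`date`, `value`) from [read_index()].
#' @param window window length in days (default 21).
#' @return `series` with an added `rolling_mean_21` column.
#' @export
rolling_mean_21 <- function(series, window = 21) {
  if (nrow(series) < window) {
    stop(sprintf("series has %d days, need at least %d", nrow(series), window))
  }
  series$rolling_mean_21 <-
    zoo::rollmeanr(series$value, k = window, fill = NA)
  series
}

#' Join rolling covariates to records by date
#'
#' Exact date join, no interpolation: every record's date must carry a
#' defined rolling value in both series.
#'
#' @param records record table with `date` (and `record_id`).
#' @param geomag,solar index series already passed through
#'   [rolling_mean_21()].
#' @return `records` with added `geomag_21` and `solar_21` columns.
#' @export
join_covariates <- function(records, geomag, solar) {
  for (nm in c("geomag", "solar")) {
    s <- if (nm == "geomag") geomag else solar
    if (!"rolling_mean_21" %in% names(s)) {
      stop(nm, " series lacks rolling_mean_21; call rolling_mean_21() first")
    }
    i <- match(records$date, s$date)
    val <- s$rolling_mean_21[i]
    bad <- is.na(val)
    if (any(bad)) {
      stop(sprintf(
        "no defined 21-day %s value for record(s) %s",
        nm, paste(utils::head(records$record_id[bad], 10), collapse = ", ")
      ))
    }
    records[[paste0(nm, "_21")]] <- val
  }
  records
}

#' Z-standardize a numeric vector (population-SD convention)
#'
#' Centers to mean zero and scales to unit standard deviation, dividing by
#' the population SD (denominator n). The transform parameters are returned
#' so fitted effects per SD can be mapped back to raw index units.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list with `z`, `mean`, `sd`.
#' @export
standardize <- function(values) {
  if (length(unique(values)) < 2) {
    stop("cannot standardize: fewer than 2 distinct values")
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(z = (values - m) / s, mean = m, sd = s)
}

#' Seasonal abundance centroid of a species
#'
#' Draws `n` points per usable week via [sample_abundance_points()], pools
#' them, and returns the arithmetic mean of longitude and latitude. Adequate
#' for mid-latitude ranges; inputs spanning the antimeridian are rejected.
#'
#' @param surfaces list of `vgm_surface` for one species over a season's weeks.
#' @param n points per week (default 10000).
#' @param seed integer seed.
#' @return named numeric `c(lon =, lat =)`.
#' @export
seasonal_centroid <- function(surfaces, n = 10000, seed = 1) {
  usable <- Filter(function(s) isTRUE(attr(s, "usable")), surfaces)
  if (length(usable) == 0) stop("no usable weeks in season")
  pts <- do.call(rbind, lapply(seq_along(usable), function(i) {
    sample_abundance_points(usable[[i]], n, seed = seed + i)
  }))
  if (diff(range(pts$lon)) > 180) {
    stop("range spans the antimeridian; arithmetic centroid undefined")
  }
  c(lon = mean(pts$lon), lat = mean(pts$lat))
}

#' Migration length between seasonal centroids
#'
#' Haversine distance (km) between the breeding and non-breeding abundance
#' centroids.
#'
#' @param breeding,nonbreeding centroids as `c(lon =, lat =)`.
#' @return distance in km.
#' @export
migration_length_km <- function(breeding, nonbreeding) {
  haversine_km(breeding[["lon"]], breeding[["lat"]],
               nonbreeding[["lon"]], nonbreeding[["lat"]])
}
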