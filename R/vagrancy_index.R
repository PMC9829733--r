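# Continuous vagrancy index: spatiotemporal rarity of a banding record,
# measured as the mean great-circle distance to its k nearest neighbours among
# n points simulated proportional to the species-week relative-abundance
# surface.

#' Great-circle (haversine) distance in kilometres
#'
#' Vectorised haversine distance on a sphere of radius 6371 km. Inputs are
#' decimal degrees.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in km. Zero if and only if the points coincide.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of arc at the equator, ~111.195 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(
    all(abs(lat1) <= 90), all(abs(lat2) <= 90),
    all(abs(lon1) <= 180), all(abs(lon2) <= 180)
  )
  r <- 6371 # km, mean Earth radius
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  # clamp for floating-point safety at antipodes
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Simulate spatial points proportional to a relative-abundance surface
#'
#' Grid cells are drawn multinomially with probability proportional to
#' abundance over unmasked cells; each draw is then jittered uniformly within
#' its cell so points are continuous rather than lattice-bound.
#'
#' @param surface an `vgm_surface` (see [read_surface()]) or a data frame with
#'   columns `lon`, `lat`, `abundance`, `mask` and a `cell_deg` attribute.
#' @param n number of points.
#' @param seed integer seed; identical seeds give identical point clouds.
#' @return data frame with columns `lon`, `lat` (`n` rows).
#' @export
sample_abundance_points <- function(surface, n, seed) {
  stopifnot(n >= 1)
  cell_deg <- attr(surface, "cell_deg")
  if (is.null(cell_deg)) stop("surface lacks a 'cell_deg' attribute")
  ok <- surface$mask & surface$abundance > 0
  if (!any(ok)) {
    stop(sprintf(
      "unusable species-week: no positive unmasked abundance (%s week %s)",
      attr(surface, "species_code"), attr(surface, "week")
    ))
  }
  w <- surface$abundance[ok]
  withr_seed(seed, {
    idx <- sample(which(ok), n, replace = TRUE, prob = w)
    data.frame(
      lon = surface$lon[idx] + stats::runif(n, -cell_deg / 2, cell_deg / 2),
      lat = surface$lat[idx] + stats::runif(n, -cell_deg / 2, cell_deg / 2)
    )
  })
}

#' Mean distance to the k nearest points
#'
#' The raw vagrancy index of one location against one simulated point cloud:
#' the mean of the `k` smallest haversine distances from `loc` to `points`.
#'
#' @param lon,lat location, decimal degrees.
#' @param points data frame with `lon`, `lat` columns.
#' @param k number of nearest neighbours (default 10).
#' @return mean distance in km.
#' @export
mean_knn_distance <- function(lon, lat, points, k = 10) {
  stopifnot(k >= 1)
  if (nrow(points) < k) {
    stop(sprintf("need at least k = %d points, got %d", k, nrow(points)))
  }
  d <- haversine_km(lon, lat, points$lon, points$lat)
  mean(sort(d, partial = k)[seq_len(k)])
}

# Week of year: day-of-year blocks of 7, capped at 52 (days 365/366 fold into
# week 52).
week_of_year <- function(date) {
  yday <- as.integer(strftime(date, "%j"))
  pmin((yday - 1L) %/% 7L + 1L, 52L)
}

# Locate each record in the surface grid; NA for records outside the grid or
# on a masked cell. Cell membership is nearest-centre within half a cell.
locate_cell <- function(surface, lon, lat) {
  cell_deg <- attr(surface, "cell_deg")
  idx <- vapply(seq_along(lon), function(i) {
    hit <- which(abs(surface$lon - lon[i]) <= cell_deg / 2 + 1e-9 &
      abs(surface$lat - lat[i]) <= cell_deg / 2 + 1e-9)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  idx
}

#' Compute the vagrancy index for a table of banding records
#'
#' For each species-week present in `records`, one cloud of `n` points is
#' simulated from that species-week abundance surface (shared by every record
#' of the group), and each record's index is the mean haversine distance to
#' its `k` nearest cloud points. Records whose location falls outside the
#' surface grid or on a masked cell are flagged `excluded_out_of_range` and
#' receive no index. Zero indices (a record sitting exactly on at least `k`
#' points) are floored to half the smallest positive index of that species so
#' the downstream gamma likelihood is well defined.
#'
#' @param records banding-record data frame (see [read_records()]).
#' @param surfaces named list of surfaces, names `"<species_code>_w<week>"`.
#' @param n points per species-week cloud (default 10000).
#' @param k nearest neighbours (default 10).
#' @param seed integer seed; clouds are deterministic given the seed.
#' @return `records` with added columns `week`, `vagrancy_km`,
#'   `excluded_out_of_range`.
#' @export
compute_vagrancy_table <- function(records, surfaces, n = 10000, k = 10,
                                   seed = 1) {
  records$week <- week_of_year(records$date)
  records$vagrancy_km <- NA_real_
  records$excluded_out_of_range <- FALSE
  groups <- unique(records[, c("species_code", "week")])
  groups <- groups[order(groups$species_code, groups$week), , drop = FALSE]
  for (g in seq_len(nrow(groups))) {
    sp <- groups$species_code[g]
    wk <- groups$week[g]
    key <- sprintf("%s_w%02d", sp, wk)
    surf <- surfaces[[key]]
    if (is.null(surf)) {
      stop(sprintf("no abundance surface for species %s week %d", sp, wk))
    }
    rows <- which(records$species_code == sp & records$week == wk)
    # per-group seed so the cloud is independent of which records are present
    cloud <- sample_abundance_points(surf, n, seed = group_seed(seed, key))
    cell <- locate_cell(surf, records$lon[rows], records$lat[rows])
    out <- is.na(cell) | !surf$mask[ifelse(is.na(cell), 1L, cell)]
    records$excluded_out_of_range[rows[out]] <- TRUE
    for (r in rows[!out]) {
      records$vagrancy_km[r] <-
        mean_knn_distance(records$lon[r], records$lat[r], cloud, k = k)
    }
  }
  # gamma support: floor exact zeros to half the species' minimum positive index
  for (sp in unique(records$species_code)) {
    rows <- which(records$species_code == sp & !records$excluded_out_of_range)
    v <- records$vagrancy_km[rows]
    if (any(v == 0, na.rm = TRUE)) {
      pos <- v[!is.na(v) & v > 0]
      floor_v <- if (length(pos)) min(pos) / 2 else 1e-3
      records$vagrancy_km[rows][!is.na(v) & v == 0] <- floor_v
    }
  }
  records
}

# Deterministic per-group seed derived from the master seed and a string key;
# kept below 2^31.
group_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 7919L + as.integer(h %% 100000L)) %% 2147483629L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
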