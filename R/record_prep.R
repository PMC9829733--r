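# Inclusion filters and density-aware thinning for banding-record tables.

#' Filter configuration for record inclusion
#'
#' Defaults encode the study's inclusion rules: wild captures only (banding
#' code 3), banding and encounter records (recaptures are inconsistently
#' reported and excluded), location precision no worse than 10 km (exactly
#' 10 km is retained; "worse than 10 km" is excluded), capture date inside
#' the species' seasonal migration window and outside any taxonomic
#' exclusion window, at least 100 season records per species (exactly 100 is
#' retained), and a per-species cap of 20000 records. The known-age
#' requirement is off for fall (unknown ages are imputed in the model) and
#' should be switched on for spring.
#'
#' @param allowed_banding_codes integer vector (default 3).
#' @param max_precision_km km (default 10).
#' @param include_record_types character vector (default banding, encounter).
#' @param season `"fall"` or `"spring"`.
#' @param min_records_per_species count (default 100).
#' @param thin_cap per-species cap (default 20000).
#' @param require_known_age drop unknown-age records (default `FALSE`).
#' @return a `filter_config` list.
#' @export
filter_config <- function(allowed_banding_codes = 3L,
                          max_precision_km = 10,
                          include_record_types = c("banding", "encounter"),
                          season = c("fall", "spring"),
                          min_records_per_species = 100L,
                          thin_cap = 20000L,
                          require_known_age = FALSE) {
  season <- match.arg(season)
  stopifnot(thin_cap > 0, min_records_per_species > 0, max_precision_km >= 0)
  structure(list(
    allowed_banding_codes = allowed_banding_codes,
    max_precision_km = max_precision_km,
    include_record_types = include_record_types,
    season = season,
    min_records_per_species = min_records_per_species,
    thin_cap = thin_cap,
    require_known_age = require_known_age
  ), class = "filter_config")
}

# Expand a month-day season window ("08-01".."11-15") to a per-date test.
in_season_window <- function(date, start_md, end_md) {
  md <- strftime(date, "%m-%d")
  if (start_md <= end_md) md >= start_md & md <= end_md
  else md >= start_md | md <= end_md # wraps the new year
}

#' Apply inclusion filters to a record table
#'
#' Rules are applied in a fixed order (banding code, record type, precision,
#' season window, taxonomic exclusion window, known age if required); each
#' excluded row is counted against the first rule it fails, so the exclusion
#' counts sum to rows in minus rows out.
#'
#' @param records banding-record data frame.
#' @param traits trait table from [read_traits()] providing season windows
#'   and exclusion windows; every species in `records` must appear.
#' @param config a [filter_config()].
#' @return list with `records` (survivors) and `exclusions` (named counts).
#' @export
filter_records <- function(records, traits, config) {
  missing_sp <- setdiff(unique(records$species_code), traits$species_code)
  if (length(missing_sp)) {
    stop("species missing from traits: ", paste(missing_sp, collapse = ", "))
  }
  rules <- c("banding_code", "record_type", "precision", "season_window",
             "exclusion_window", "unknown_age")
  excl <- stats::setNames(integer(length(rules)), rules)
  if (nrow(records) == 0) {
    return(list(records = records, exclusions = as.list(excl)))
  }
  ti <- match(records$species_code, traits$species_code)
  start_md <- if (config$season == "fall") traits$fall_start else traits$spring_start
  end_md <- if (config$season == "fall") traits$fall_end else traits$spring_end

  fail <- rep(NA_character_, nrow(records))
  mark <- function(fail, bad, rule) {
    fail[is.na(fail) & bad] <- rule
    fail
  }
  fail <- mark(fail, !(records$banding_code %in% config$allowed_banding_codes),
               "banding_code")
  fail <- mark(fail, !(records$record_type %in% config$include_record_types),
               "record_type")
  fail <- mark(fail, records$precision_km > config$max_precision_km,
               "precision")
  in_season <- vapply(seq_len(nrow(records)), function(r) {
    in_season_window(records$date[r], start_md[ti[r]], end_md[ti[r]])
  }, logical(1))
  fail <- mark(fail, !in_season, "season_window")
  in_excl <- vapply(seq_len(nrow(records)), function(r) {
    w <- traits$exclusion_windows[[ti[r]]]
    if (is.null(w) || nrow(w) == 0) return(FALSE)
    any(records$date[r] >= w$start & records$date[r] <= w$end)
  }, logical(1))
  fail <- mark(fail, in_excl, "exclusion_window")
  if (config$require_known_age) {
    fail <- mark(fail, records$age_class == "unknown", "unknown_age")
  }
  tab <- table(factor(fail, levels = rules))
  excl[names(tab)] <- as.integer(tab)
  list(records = records[is.na(fail), , drop = FALSE],
       exclusions = as.list(excl))
}

#' Species retained after the minimum-record rule
#'
#' Species with fewer than `min_records_per_species` season records are
#' excluded from the analysis of that season (a count of exactly the
#' threshold is retained).
#'
#' @param records season-filtered record table.
#' @param config a [filter_config()].
#' @return character vector of retained species codes, with attribute
#'   `"dropped"` naming the excluded species and their counts.
#' @export
species_season_inclusion <- function(records, config) {
  counts <- table(records$species_code)
  keep <- names(counts)[counts >= config$min_records_per_species]
  dropped <- counts[counts < config$min_records_per_species]
  if (length(keep) == 0) {
    warning("no species meets the minimum record count (",
            config$min_records_per_species, ")")
  }
  structure(keep, dropped = dropped)
}

#' Thin over-represented species, down-weighting dense years
#'
#' Per species, if the record count exceeds `cap`, exactly `cap` rows are
#' kept with per-row inclusion probability inversely proportional to the
#' number of that species' records in that row's year. Because every row of
#' a year shares the same weight, this law is equivalent to giving each year
#' an equal share of the cap — up to exhaustion of small years, whose
#' records are all kept (water-filling) — and drawing a simple random sample
#' within each year. Two years with 30,000 and 10,000 records and a cap of
#' 20,000 therefore contribute 10,000 records each. Deterministic under a
#' fixed seed.
#'
#' @param records record table.
#' @param cap per-species maximum (default 20000).
#' @param seed integer seed.
#' @return thinned record table.
#' @export
thin_records <- function(records, cap = 20000, seed = 1) {
  stopifnot(cap > 0)
  year <- as.integer(strftime(records$date, "%Y"))
  withr_seed(seed, {
    keep <- unlist(lapply(unique(records$species_code), function(sp) {
      rows <- which(records$species_code == sp)
      if (length(rows) <= cap) return(rows)
      ny <- table(year[rows])
      m <- equal_year_allocation(as.integer(ny), cap)
      unlist(lapply(seq_along(ny), function(k) {
        ry <- rows[year[rows] == as.integer(names(ny)[k])]
        if (m[k] >= length(ry)) ry else ry[sample.int(length(ry), m[k])]
      }))
    }))
    records[sort(keep), , drop = FALSE]
  })
}

# Integer per-year allocation under the inverse-density inclusion law:
# expected count per year is min(c, n_y) with the water level c chosen so
# the total equals cap; fractional remainders are assigned randomly with
# probability proportional to the fractional parts.
equal_year_allocation <- function(n_y, cap) {
  stopifnot(sum(n_y) >= cap)
  lo <- 0
  hi <- max(n_y)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(pmin(mid, n_y)) < cap) lo <- mid else hi <- mid
  }
  m <- pmin(hi, n_y)
  base <- floor(m)
  frac <- m - base
  rem <- cap - sum(base)
  if (rem > 0) {
    cand <- which(frac > 1e-9)
    if (length(cand) < rem) cand <- seq_along(n_y)[base < n_y]
    extra <- cand[sample.int(length(cand), rem, prob = frac[cand] + 1e-9)]
    base[extra] <- base[extra] + 1
  }
  base
}
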