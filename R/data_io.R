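# Readers and writers for the on-disk artifacts: banding-record tables,
# gridded weekly abundance surfaces, daily index series, species traits and
# phylogenies. All tabular files are CSV with ISO-8601 dates; trees are
# newick; generative truth is JSON.

RECORD_COLS <- c(
  "record_id", "species_code", "date", "lon", "lat",
  "precision_km", "age_class", "record_type", "banding_code"
)
AGE_LEVELS <- c("adult", "young", "unknown")
RECORD_TYPES <- c("banding", "encounter", "recapture")

#' Read a banding-record table
#'
#' Rows are validated against the schema invariants (coordinates in range,
#' nonnegative precision, known categorical levels, parseable dates); invalid
#' rows are dropped with a warning that lists their row numbers, and the
#' dropped subset is attached as attribute `"rejected"`. A blank or missing
#' age field is read as `"unknown"` — unaged birds are data, not errors.
#'
#' @param path CSV file with columns `record_id, species_code, date, lon,
#'   lat, precision_km, age_class, record_type, banding_code`.
#' @return data frame of valid records, `date` as `Date`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLS, names(df))
  if (length(missing_cols)) {
    stop("record file ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$record_id <- as.character(df$record_id)
  df$species_code <- as.character(df$species_code)
  df <- df[, c(RECORD_COLS, setdiff(names(df), RECORD_COLS))]
  validate_records(df, context = path)
}

#' @rdname read_records
#' @param records a banding-record data frame.
#' @export
write_records <- function(records, path) {
  out <- records
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Row-level validation shared by the reader and the synthetic generator.
validate_records <- function(df, context = "records") {
  if (nrow(df) == 0) {
    df$date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    return(df)
  }
  age <- as.character(df$age_class)
  age[is.na(age) | age == ""] <- "unknown"
  df$age_class <- age
  date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- is.na(date) |
    is.na(df$lon) | abs(df$lon) > 180 |
    is.na(df$lat) | abs(df$lat) > 90 |
    is.na(df$precision_km) | df$precision_km < 0 |
    !(df$age_class %in% AGE_LEVELS) |
    !(df$record_type %in% RECORD_TYPES)
  df$date <- date
  if (any(bad)) {
    warning(sprintf(
      "%s: rejected %d invalid row(s): %s", context, sum(bad),
      paste(utils::head(which(bad), 20), collapse = ", ")
    ))
    rejected <- df[bad, , drop = FALSE]
    df <- df[!bad, , drop = FALSE]
    attr(df, "rejected") <- rejected
  }
  df
}

#' Read or write a gridded weekly abundance surface
#'
#' Surfaces are long-format CSV: one row per grid cell with columns
#' `species_code, week, lon, lat, abundance, mask` (`lon`/`lat` are cell
#' centres in decimal degrees, `mask` is 1 inside the modeled range).
#' A surface whose unmasked cells are all zero is flagged unusable via
#' attribute `"usable" = FALSE`.
#'
#' @param path CSV file as above; one species-week per file.
#' @return an `vgm_surface`: the cell table with attributes `species_code`,
#'   `week`, `cell_deg`, `usable`.
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_code", "week", "lon", "lat", "abundance", "mask")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("surface file ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$abundance < 0)) stop("surface ", path, " has negative abundance")
  df$mask <- as.logical(df$mask)
  if (any(!df$mask & df$abundance > 0)) {
    stop("surface ", path, " carries abundance on masked-out cells")
  }
  as_surface(df[, need])
}

as_surface <- function(df) {
  lons <- sort(unique(df$lon))
  cell_deg <- if (length(lons) > 1) min(diff(lons)) else {
    lats <- sort(unique(df$lat))
    if (length(lats) > 1) min(diff(lats)) else stop(
      "degenerate grid: a single cell cannot define a surface")
  }
  out <- df
  attr(out, "species_code") <- df$species_code[1]
  attr(out, "week") <- df$week[1]
  attr(out, "cell_deg") <- cell_deg
  attr(out, "usable") <- any(df$mask & df$abundance > 0)
  class(out) <- c("vgm_surface", "data.frame")
  out
}

#' @rdname read_surface
#' @param surface an `vgm_surface`.
#' @export
write_surface <- function(surface, path) {
  df <- as.data.frame(surface)
  df$mask <- as.integer(df$mask)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a daily index series
#'
#' A dated scalar series (geomagnetic Ap-like or sunspot-like). Dates must be
#' strictly increasing and contiguous: any skipped day is an error naming the
#' first gap, because the 21-day rolling window assumes daily coverage.
#'
#' @param path CSV with columns `date, value`.
#' @param name series label, `"geomagnetic"` or `"solar"`; defaults to a
#'   `name` column if present.
#' @return data frame `date` (`Date`), `value`, with attribute `name`.
#' @export
read_index <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(df))) {
    stop("index file ", path, " needs columns date, value")
  }
  if (is.null(name)) name <- if ("name" %in% names(df)) df$name[1] else "index"
  df$date <- as.Date(df$date)
  validate_index(data.frame(date = df$date, value = df$value), name,
                 context = path)
}

validate_index <- function(df, name, context = "index") {
  if (any(is.na(df$date))) stop(context, ": unparseable dates")
  dd <- diff(as.integer(df$date))
  if (any(dd <= 0)) stop(context, ": dates not strictly increasing")
  if (any(dd > 1)) {
    g <- which(dd > 1)[1]
    stop(sprintf("%s: gap in daily series after %s (next is %s)",
                 context, df$date[g], df$date[g + 1]))
  }
  if (any(df$value < 0)) stop(context, ": index values must be nonnegative")
  attr(df, "name") <- name
  class(df) <- c("vgm_index", "data.frame")
  df
}

#' @rdname read_index
#' @param series an index data frame.
#' @export
write_index <- function(series, path) {
  out <- data.frame(date = format(series$date, "%Y-%m-%d"),
                    value = series$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a species-trait table
#'
#' Columns: `species_code, migration_length_km, breeding_latitude_deg,
#' wintering_latitude_deg, diel, fall_start, fall_end, spring_start,
#' spring_end, exclusion_windows`. Seasonal windows are month-day strings
#' (`"08-01"`) applied each study year; `exclusion_windows` is a
#' semicolon-separated list of `YYYY-MM-DD:YYYY-MM-DD` date ranges (possibly
#' empty) within which records of that species are taxonomically
#' indeterminate and must be dropped.
#'
#' @param path CSV file.
#' @return data frame, with parsed `exclusion_windows` as a list column of
#'   two-column date data frames.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species_code = "character"))
  need <- c("species_code", "migration_length_km", "breeding_latitude_deg",
            "diel", "fall_start", "fall_end", "spring_start", "spring_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("traits file ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$migration_length_km < 0, na.rm = TRUE)) {
    stop("traits: migration_length_km must be nonnegative")
  }
  if (!"exclusion_windows" %in% names(df)) df$exclusion_windows <- ""
  df$exclusion_windows <- lapply(df$exclusion_windows, parse_windows)
  df
}

parse_windows <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  start <- as.Date(vapply(parts, `[`, "", 1))
  end <- as.Date(vapply(parts, `[`, "", 2))
  if (any(is.na(start) | is.na(end)) || any(start > end)) {
    stop("malformed exclusion window: ", s)
  }
  data.frame(start = start, end = end)
}

#' @rdname read_traits
#' @param traits a trait data frame (list-column `exclusion_windows` allowed).
#' @export
write_traits <- function(traits, path) {
  out <- traits
  if (is.list(out$exclusion_windows)) {
    out$exclusion_windows <- vapply(out$exclusion_windows, function(w) {
      if (is.null(w) || nrow(w) == 0) "" else
        paste(sprintf("%s:%s", w$start, w$end), collapse = ";")
    }, "")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phylogeny from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that turns a silent parse failure
#' into an error carrying the offending path.
#'
#' @param path newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("unparseable newick in ", path)
  tr
}
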