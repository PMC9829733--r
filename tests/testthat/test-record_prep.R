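# Inclusion filters and density-aware thinning.

make_toy_records <- function() {
  data.frame(
    record_id = sprintf("t%02d", 1:10),
    species_code = "SP01",
    date = as.Date(c("2001-09-01", "2001-09-02", "2001-09-03", "2001-09-04",
                     "2001-09-05", "2001-02-01", "2001-09-07", "2001-09-06",
                     "2001-09-09", "2001-09-12")),
    lon = -90, lat = 40,
    precision_km = c(0, 0, 11, 10, 0, 0, 0, 0, 0, 0),
    age_class = c("adult", "young", "adult", "adult", "adult", "adult",
                  "adult", "unknown", "adult", "adult"),
    record_type = c("banding", "banding", "banding", "banding", "recapture",
                    "banding", "banding", "banding", "banding", "banding"),
    banding_code = c(3L, 8L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

toy_traits <- data.frame(
  species_code = "SP01", migration_length_km = 2000,
  breeding_latitude_deg = 45, wintering_latitude_deg = 25,
  diel = "nocturnal",
  fall_start = "08-01", fall_end = "11-15",
  spring_start = "04-01", spring_end = "06-01",
  stringsAsFactors = FALSE
)
toy_traits$exclusion_windows <- list(
  data.frame(start = as.Date("2001-09-09"), end = as.Date("2001-09-11"))
)

test_that("each inclusion rule excludes its violating record exactly once", {
  rec <- make_toy_records()
  out <- filter_records(rec, toy_traits, filter_config(season = "fall"))
  # t02 fails banding code, t03 precision (11 > 10), t04 retained (== 10 km),
  # t05 recapture, t06 outside the fall window, t09+t10 in the exclusion
  # window (t10 is outside it), t08 unknown age retained (fall keeps them)
  expect_equal(out$records$record_id,
               c("t01", "t04", "t07", "t08", "t10"))
  expect_equal(out$exclusions$banding_code, 1)
  expect_equal(out$exclusions$record_type, 1)
  expect_equal(out$exclusions$precision, 1)
  expect_equal(out$exclusions$season_window, 1)
  expect_equal(out$exclusions$exclusion_window, 1)
  expect_equal(out$exclusions$unknown_age, 0)
  expect_equal(sum(unlist(out$exclusions)),
               nrow(rec) - nrow(out$records))
})

test_that("the spring known-age switch drops unknown-age records", {
  rec <- make_toy_records()
  cfg <- filter_config(season = "fall", require_known_age = TRUE)
  out <- filter_records(rec, toy_traits, cfg)
  expect_false("t08" %in% out$records$record_id)
  expect_equal(out$exclusions$unknown_age, 1)
})

test_that("filtering is idempotent and total on empty input", {
  rec <- make_toy_records()
  cfg <- filter_config(season = "fall")
  once <- filter_records(rec, toy_traits, cfg)
  twice <- filter_records(once$records, toy_traits, cfg)
  expect_equal(twice$records, once$records)
  expect_true(all(unlist(twice$exclusions) == 0))
  empty <- filter_records(rec[0, ], toy_traits, cfg)
  expect_equal(nrow(empty$records), 0)
  expect_true(all(unlist(empty$exclusions) == 0))
})

test_that("species absent from the trait table are a hard error", {
  rec <- make_toy_records()
  rec$species_code[1] <- "SP99"
  expect_error(filter_records(rec, toy_traits, filter_config()), "SP99")
})

test_that("the minimum-record rule keeps exactly-at-threshold species", {
  rec <- data.frame(
    species_code = c(rep("A", 99), rep("B", 100), rep("C", 150))
  )
  keep <- species_season_inclusion(rec, filter_config())
  expect_equal(sort(as.character(keep)), c("B", "C"))
  expect_equal(names(attr(keep, "dropped")), "A")
  expect_warning(
    none <- species_season_inclusion(rec[rec$species_code == "A", , drop = FALSE],
                                     filter_config(min_records_per_species = 200)),
    "no species"
  )
  expect_equal(length(none), 0)
})

test_that("thinning passes under-cap species through unchanged", {
  rec <- tiny_records
  out <- thin_records(rec, cap = 20000, seed = 1)
  expect_equal(out$record_id, rec$record_id)
})

test_that("thinning caps over-cap species and keeps every year represented", {
  set.seed(1)
  n_a <- 300; n_b <- 100
  rec <- data.frame(
    record_id = sprintf("r%03d", 1:(n_a + n_b)),
    species_code = "SP01",
    date = as.Date(c(
      sample(seq(as.Date("2001-06-01"), as.Date("2001-10-01"), by = "day"),
             n_a, replace = TRUE),
      sample(seq(as.Date("2002-06-01"), as.Date("2002-10-01"), by = "day"),
             n_b, replace = TRUE)
    )),
    stringsAsFactors = FALSE
  )
  out <- thin_records(rec, cap = 200, seed = 2)
  expect_equal(nrow(out), 200)
  yrs <- table(strftime(out$date, "%Y"))
  expect_equal(sort(names(yrs)), c("2001", "2002"))
  # deterministic under a fixed seed
  expect_identical(out, thin_records(rec, cap = 200, seed = 2))
  one <- thin_records(rec, cap = 1, seed = 3)
  expect_equal(nrow(one), 1)
})

test_that("thinning gives each year an equal share up to exhaustion", {
  n_a <- 300; n_b <- 100
  rec <- data.frame(
    record_id = sprintf("r%03d", 1:(n_a + n_b)),
    species_code = "SP01",
    date = c(rep(as.Date("2001-09-01"), n_a), rep(as.Date("2002-09-01"), n_b)),
    stringsAsFactors = FALSE
  )
  # no year saturated: exactly 60 from each year under any seed
  counts <- sapply(1:20, function(s) {
    out <- thin_records(rec, cap = 120, seed = s)
    table(factor(strftime(out$date, "%Y"), levels = c("2001", "2002")))
  })
  expect_true(all(counts == 60))
  # sparse year exhausted: it keeps all 100, the dense year fills the rest
  out <- thin_records(rec, cap = 250, seed = 1)
  tab <- table(strftime(out$date, "%Y"))
  expect_equal(as.integer(tab[["2002"]]), 100)
  expect_equal(as.integer(tab[["2001"]]), 150)
})

test_that("fractional year allocations keep the cap exact", {
  rec <- data.frame(
    record_id = sprintf("q%03d", 1:250),
    species_code = "SP01",
    date = c(rep(as.Date("2001-09-01"), 50), rep(as.Date("2002-09-01"), 80),
             rep(as.Date("2003-09-01"), 120)),
    stringsAsFactors = FALSE
  )
  for (s in 1:20) {
    out <- thin_records(rec, cap = 151, seed = s)
    expect_equal(nrow(out), 151)
  }
})
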