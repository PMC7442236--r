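test_that("larval reader computes day-count ages and keeps rows", {
  path <- write_tmp_csv(c(
    "wetland_id,capture_date,pond_fill_date,svl_mm",
    "W01,2011-01-15,2010-11-01,14.2",
    "W01,2011-02-01,2010-11-01,18.0",
    "W02,2011-03-10,2010-12-01,25.5"))
  rec <- read_larval_csv(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$age_years[1], 75 / 365.25)
  expect_equal(rec$age_years[1], 0.2053388090349076, tolerance = 1e-12)
  expect_equal(rec$svl_mm, c(14.2, 18.0, 25.5))
})

test_that("larval reader handles the empty file and reports bad rows", {
  empty <- write_tmp_csv("wetland_id,capture_date,pond_fill_date,svl_mm")
  expect_equal(nrow(read_larval_csv(empty)), 0)

  missing_col <- write_tmp_csv(c("wetland_id,capture_date,svl_mm",
                                 "W01,2011-01-15,14.2"))
  expect_error(read_larval_csv(missing_col), "missing column")

  bad_date <- write_tmp_csv(c(
    "wetland_id,capture_date,pond_fill_date,svl_mm",
    "W01,2011-01-15,2010-11-01,14.2",
    "W01,not-a-date,2010-11-01,15.0"))
  expect_error(read_larval_csv(bad_date), "row\\(s\\) 3")

  # pond fill after capture: zero or negative age
  inverted <- write_tmp_csv(c(
    "wetland_id,capture_date,pond_fill_date,svl_mm",
    "W01,2010-10-01,2010-11-01,14.2"))
  expect_error(read_larval_csv(inverted), "age_years")
})

test_that("metamorph reader parses exactly and validates lengths", {
  path <- write_tmp_csv(c("wetland_id,cohort_year,svl_mm",
                          "W01,2015,39.3", "W01,2016,44.1"))
  rec <- read_metamorph_csv(path)
  expect_equal(nrow(rec), 2)
  expect_identical(rec$svl_mm[1], 39.3)
  expect_identical(rec$cohort_year, c(2015L, 2016L))

  neg <- write_tmp_csv(c("wetland_id,cohort_year,svl_mm", "W01,2015,-1"))
  expect_error(read_metamorph_csv(neg), "positive")
})

test_that("adult reader groups, sorts, and derives offsets", {
  path <- write_tmp_csv(c("individual_id,capture_date,svl_mm",
                          "A2,2011-11-01,60.0",
                          "A1,2010-11-01,52.0",
                          "A2,2010-11-05,57.5",
                          "A1,2011-11-01,55.0"))
  hist <- read_adult_captures_csv(path)
  expect_length(hist, 2)
  expect_equal(hist$A1$time_offset_years, c(0, 365 / 365.25))
  expect_equal(hist$A1$time_offset_years[2], 0.9993155373032170,
               tolerance = 1e-12)
  expect_equal(hist$A1$svl_mm, c(52.0, 55.0))
  expect_equal(hist$A2$svl_mm, c(57.5, 60.0))  # sorted despite file order
})

test_that("offset computation is independent of row order", {
  rows <- c("A1,2010-11-01,52.0", "A1,2011-11-01,55.0",
            "A1,2013-04-20,57.0", "A2,2012-01-01,58.0")
  header <- "individual_id,capture_date,svl_mm"
  h1 <- read_adult_captures_csv(write_tmp_csv(c(header, rows)))
  h2 <- read_adult_captures_csv(write_tmp_csv(c(header, rev(rows))))
  expect_identical(h1, h2)
})

test_that("adult reader rejects duplicates and single captures work", {
  dup <- write_tmp_csv(c("individual_id,capture_date,svl_mm",
                         "A1,2010-11-01,52.0", "A1,2010-11-01,52.5"))
  expect_error(read_adult_captures_csv(dup), "duplicate")

  single <- write_tmp_csv(c("individual_id,capture_date,svl_mm",
                            "A1,2010-11-01,52.0"))
  hist <- read_adult_captures_csv(single)
  expect_length(hist, 1)
  expect_identical(hist$A1$time_offset_years, 0)
})

test_that("capture_history enforces its invariants", {
  expect_error(capture_history("A", "2010-11-01", c(0.5, 1), c(50, 51)),
               "offset 0")
  expect_error(capture_history("A", "2010-11-01", c(0, 1, 1), c(50, 51, 52)),
               "strictly increasing")
  expect_error(capture_history("A", "2010-11-01", 0, -3), "positive")
})

test_that("validate_dataset counts streams and recaptures", {
  ds <- tiny_dataset()
  rep <- validate_dataset(ds)
  expect_equal(rep$counts,
               list(n_larvae = 2L, n_metamorphs = 2L, n_adults = 2L,
                    n_adults_recaptured = 1L))
  expect_length(rep$violations, 0)
  expect_equal(rep$svl_summary$adults$max, 58.5)

  empty <- validate_dataset(growth_dataset())
  expect_equal(unlist(empty$counts), c(n_larvae = 0, n_metamorphs = 0,
                                       n_adults = 0,
                                       n_adults_recaptured = 0))

  # ten adults each captured twice
  adults <- lapply(1:10, function(i) {
    capture_history(paste0("B", i), "2014-11-01", c(0, 1), c(50, 52))
  })
  rep2 <- validate_dataset(growth_dataset(adults = adults))
  expect_equal(rep2$counts$n_adults, 10L)
  expect_equal(rep2$counts$n_adults_recaptured, 10L)
})

test_that("validation reports serialise to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(validate_dataset(tiny_dataset()), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$counts$n_adults_recaptured, 1)
  expect_equal(back$svl_summary$larvae$mean, mean(c(12.0, 22.5)))
})

test_that("write-then-read round trip reproduces every field", {
  sim <- simulate_dataset(sim_config(n_larvae = 25, n_metamorphs = 20,
                                     n_adults = 15, seed = 99))
  dir <- withr::local_tempdir()
  write_dataset_csv(sim$dataset, dir)
  back <- growth_dataset(
    read_larval_csv(file.path(dir, "larvae.csv")),
    read_metamorph_csv(file.path(dir, "metamorphs.csv")),
    read_adult_captures_csv(file.path(dir, "adult_captures.csv")))
  expect_equal(back$larvae$svl_mm, sim$dataset$larvae$svl_mm)
  expect_equal(back$larvae$age_years, sim$dataset$larvae$age_years)
  expect_equal(back$metamorphs, sim$dataset$metamorphs)
  ids <- names(sim$dataset$adults)
  for (id in ids) {
    expect_equal(back$adults[[id]]$svl_mm, sim$dataset$adults[[id]]$svl_mm)
    expect_equal(back$adults[[id]]$time_offset_years,
                 sim$dataset$adults[[id]]$time_offset_years)
  }
})
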