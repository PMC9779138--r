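test_that("read_monitoring_csv parses, marks missing cells, completes the grid", {
  p <- write_toy_csv(c(
    "timestamp,O3,SO2",
    "2011-01-01T00:00:00,10.0,5.0",
    "2011-01-01T01:00:00,12.0,",
    "2011-01-01T02:00:00,11.5,4.0"))
  s <- read_monitoring_csv(p)
  expect_s3_class(s, "monitoring_series")
  expect_equal(nrow(s), 3)
  expect_true(is.na(s$SO2[2]))
  expect_equal(s$O3, c(10, 12, 11.5))

  # gap in the hourly grid filled with an all-missing row
  p2 <- write_toy_csv(c(
    "timestamp,O3",
    "2011-01-01T00:00:00,10.0",
    "2011-01-01T02:00:00,11.0"))
  s2 <- read_monitoring_csv(p2)
  expect_equal(nrow(s2), 3)
  expect_true(is.na(s2$O3[2]))
  expect_equal(diff(as.numeric(s2$timestamp)), c(3600, 3600))

  # duplicate timestamp names the offender
  p3 <- write_toy_csv(c(
    "timestamp,O3",
    "2011-01-01T05:00:00,10.0",
    "2011-01-01T05:00:00,11.0"))
  expect_error(read_monitoring_csv(p3), "05:00")

  # unknown variable in schema
  expect_error(read_monitoring_csv(p, schema = c(XX = "O3")), "unknown variable")
})

test_that("monitoring series invariants are enforced", {
  ts <- seq(as.POSIXct("2011-01-01", tz = "UTC"), by = 3600, length.out = 3)
  expect_error(monitoring_series(ts, list(O3 = c(1, -2, 3))), "negative O3")
  expect_error(monitoring_series(ts, list(RH = c(50, 120, 60))), "RH")
  expect_error(monitoring_series(ts[c(1, 1, 2)], list(O3 = c(1, 2, 3))),
               "duplicate")
  expect_error(monitoring_series(ts[c(1, 3, 2)], list(O3 = c(1, 2, 3))),
               "grid")
  expect_silent(monitoring_series(ts, list(O3 = c(1, NA, 3), RH = c(0, 50, 100))))
})

test_that("CSV round trip preserves values and missingness", {
  s <- complete_synthetic_series(seed = 3, years = 2011)
  s$O3[5:10] <- NA
  p <- tempfile(fileext = ".csv")
  write_monitoring_csv(s, p)
  s2 <- read_monitoring_csv(p, station_id = attr(s, "station_id"))
  expect_equal(s2$timestamp, s$timestamp)
  expect_equal(s2$O3, s$O3, tolerance = 1e-12)
  expect_equal(s2$PM10, s$PM10, tolerance = 1e-12)
})

test_that("encode_time conventions", {
  t1 <- as.POSIXct("2011-01-01 00:00", tz = "UTC")
  expect_equal(encode_time(t1, "linear"), data.frame(D = 1, H = 0))
  # calendar arithmetic: 2011-06-15 is day 166 of a non-leap year
  t2 <- as.POSIXct("2011-06-15 13:00", tz = "UTC")
  expect_equal(encode_time(t2, "linear"), data.frame(D = 166, H = 13))

  # cosine hour encoding: the midnight wrap step has the same magnitude as the
  # 00->01 step (cosine symmetry) and is no larger than any other step
  hrs <- as.POSIXct(sprintf("2011-01-01 %02d:00", 0:23), tz = "UTC")
  Hc <- encode_time(hrs, "cosine")$H
  steps <- abs(diff(c(Hc, Hc[1])))
  expect_equal(steps[24], steps[1], tolerance = 1e-12)
  expect_lte(steps[24], max(steps[1:23]))
  expect_true(all(Hc >= -1 & Hc <= 1))
  # day encoding peaks at mid-year
  days <- as.POSIXct(sprintf("2011-%02d-01", 1:12), tz = "UTC")
  Dc <- encode_time(days, "cosine")$D
  expect_equal(which.max(Dc), 7) # July
})

test_that("expected_case_count matches calendar arithmetic", {
  expect_identical(expected_case_count("2011-01-01", "2016-12-31"), 52608L)
  expect_identical(expected_case_count("2011-01-01", "2011-12-31"), 8760L)
  expect_identical(expected_case_count("2012-01-01", "2012-12-31"), 8784L)
  expect_error(expected_case_count("2012-01-02", "2012-01-01"), "precedes")
  # property: 8760 + 24 * [leap] for all years 1901-2099
  for (y in seq(1901, 2099, by = 7)) {
    leap <- (y %% 4 == 0) && (y %% 100 != 0 || y %% 400 == 0)
    expect_identical(
      expected_case_count(sprintf("%d-01-01", y), sprintf("%d-12-31", y)),
      8760L + 24L * leap)
  }
})

test_that("build_case_table keeps exactly the complete cases, in order", {
  ts <- seq(as.POSIXct("2011-03-01", tz = "UTC"), by = 3600, length.out = 10)
  vals <- list(O3 = c(1:4, NA, 6:10), T = c(1:8, NA, 10), NO = 1:10)
  s <- monitoring_series(ts, vals)
  spec <- variable_spec("O3", c("D", "H", "T", "NO"))
  tab <- build_case_table(s, spec)
  expect_equal(nrow(tab), 8)
  expect_equal(names(tab), c("D", "H", "T", "NO", "O3"))
  expect_equal(tab$NO, c(1:4, 6:8, 10)) # chronological
  # conservation: kept + removed = series length
  expect_equal(nrow(tab) + 2, nrow(s))

  expect_error(build_case_table(s, variable_spec("O3", c("D", "H", "CO"))),
               "lacks required")
  # fully complete series keeps every hour
  tab2 <- build_case_table(s, variable_spec("NO", c("D", "H")))
  expect_equal(nrow(tab2), 10)
  # all-missing target -> no complete cases
  s$O3[] <- NA
  expect_error(build_case_table(s, spec), "no complete cases")
})

test_that("split_train_valid_test honors fractions and is reproducible", {
  tab <- linear_case_table(100)
  sp <- split_train_valid_test(tab, seed = 42)
  expect_equal(as.vector(table(sp)), c(70, 15, 15))
  expect_identical(sp, split_train_valid_test(tab, seed = 42))
  expect_false(identical(as.character(sp),
                         as.character(split_train_valid_test(tab, seed = 43))))

  # largest-remainder apportionment
  sp20 <- split_train_valid_test(linear_case_table(20), seed = 1)
  expect_equal(as.vector(table(sp20)), c(14, 3, 3))
  expect_error(split_train_valid_test(linear_case_table(6), seed = 1),
               "at least 7")

  # property: partition with counts within 1 of the exact fractions
  for (n in c(7, 11, 23, 57, 101, 999)) {
    spn <- split_train_valid_test(linear_case_table(n), seed = n)
    counts <- as.vector(table(spn))
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * c(0.70, 0.15, 0.15)) <= 1))
  }
})

test_that("default variable specs mirror the station predictor sets", {
  sp <- default_variable_spec("O3", "zloty_potok")
  expect_length(sp$predictors, 11) # H, D, 5 pollutants, WS, T, I, RH
  expect_false("O3" %in% sp$predictors)
  sp2 <- default_variable_spec("PM10", "zabrze")
  expect_false("RH" %in% sp2$predictors)
  expect_true("CO" %in% sp2$predictors)
  expect_error(default_variable_spec("CO", "zloty_potok"), "not measured")
  expect_error(variable_spec("O3", c("O3", "T")), "cannot be one of")
  expect_error(variable_spec("O3", character(0)), "non-empty")
})
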