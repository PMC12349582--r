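test_that("sub-daily readings aggregate to daily means", {
  d <- rep(as.Date("2005-06-01"), 8)
  expect_equal(aggregateDaily(d, rep(12, 8))$value, 12)
  expect_equal(aggregateDaily(d, seq(0, 21, by = 3))$value, 10.5)
  dd <- c(rep(as.Date("2005-06-01"), 2), rep(as.Date("2005-06-03"), 2))
  expect_error(aggregateDaily(dd, 1:4), class = "missingDataError")
})

test_that("daily series resample to composite means", {
  cal <- compositeCalendar(2001, 1)
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  daily <- data.frame(date = days, value = rep(3.5, length(days)))
  expect_equal(resampleToComposites(daily, cal), rep(3.5, 46))
  ## hand case: values 1..8 in the first window -> 4.5
  daily2 <- daily
  daily2$value[1:8] <- 1:8
  expect_equal(resampleToComposites(daily2, cal)[1], 4.5)
  ## final composite of a non-leap year averages its 5 days
  daily3 <- daily
  daily3$value[match(cal$date[46] + 0:4, daily3$date)] <- c(1, 2, 3, 4, 10)
  expect_equal(resampleToComposites(daily3, cal)[46], 4)
  ## partial coverage errors
  expect_error(resampleToComposites(daily[-5, ], cal),
               class = "missingDataError")
})

test_that("grid validity filter applies the mean-LAI threshold inclusively", {
  nt <- 46L
  sm <- matrix(250, 3, nt); ta <- matrix(8, 3, nt)
  la <- rbind(rep(0.05, nt),      # below threshold -> dropped
              rep(0.1, nt),       # exactly at threshold -> kept
              rep(2, nt))         # clearly vegetated -> kept
  x <- make_grids(sm, ta, la)
  expect_equal(unname(filterValidGrids(x)), c(FALSE, TRUE, TRUE))
  ## grids with missing values in any variable are dropped
  sm2 <- sm; sm2[3, 10] <- NA
  x2 <- make_grids(sm2, ta, la)
  expect_equal(unname(filterValidGrids(x2)), c(FALSE, TRUE, FALSE))
  ## all vegetated -> all kept
  x3 <- make_grids(sm, ta, la + 1)
  expect_true(all(filterValidGrids(x3)))
  expect_error(filterValidGrids(x[, 0]), class = "invalidArgumentError")
})

test_that("min-max normalization uses the fixed physical ranges", {
  expect_equal(normalizeValues(25, "temperature"), 0.75)
  expect_equal(normalizeValues(0, "soil_moisture"), 0)
  expect_equal(normalizeValues(10, "lai"), 1)
  set.seed(1)
  v <- runif(100, 0, 10)
  expect_equal(denormalizeValues(normalizeValues(v, "lai"), "lai"), v,
               tolerance = 1e-12)
  err <- tryCatch(normalizeValues(c(20, 60), "temperature"),
                  error = identity)
  expect_s3_class(err, "rangeViolationError")
  expect_match(conditionMessage(err), "temperature")
  expect_match(conditionMessage(err), "index 2")
})

test_that("window construction yields T - w + 1 samples matching naive enumeration", {
  nt <- 20L
  set.seed(7)
  sm <- matrix(runif(nt, 100, 400), 1)
  ta <- matrix(runif(nt, -5, 25), 1)
  la <- matrix(runif(nt, 0, 6), 1)
  x <- make_grids(sm, ta, la)
  s <- buildSamples(x, window = 7)
  expect_equal(length(s), nt - 7 + 1)
  ## naive enumeration oracle
  for (i in c(1, 5, 14)) {
    expect_equal(sampleInputs(s)[i, , 1], (sm[1, i:(i + 6)] - 0) / 1000)
    expect_equal(sampleInputs(s)[i, , 2], (ta[1, i:(i + 6)] + 50) / 100)
    expect_equal(sampleTargets(s)[i], la[1, i + 6] / 10)
    expect_equal(sampleDates(s)[i], compositeDates(x)[i + 6])
  }
  ## exactly one sample when T == window
  s1 <- buildSamples(x[, 1:7], window = 7)
  expect_equal(length(s1), 1L)
  expect_error(buildSamples(x[, 1:6], window = 7),
               class = "insufficientDataError")
})

test_that("a 1012-composite series yields 1006 windows per grid", {
  x <- simulateLaiGrids(gridSpec(1, 1, "forest"), 22, seed = 1,
                        start_year = 2000)
  expect_equal(ncol(x), 1012)
  expect_equal(length(buildSamples(x)), 1006)
})

test_that("chronological split uses floor rounding and never leaks", {
  nt <- 16L  # 10 samples with window 7
  x <- make_grids(matrix(250, 1, nt), matrix(8, 1, nt),
                  matrix(2, 1, nt))
  s <- splitChronological(buildSamples(x))
  expect_equal(as.integer(table(sampleSplits(s))[c("train", "val", "test")]),
               c(7L, 1L, 2L))
  ## n = 1006 -> (704, 100, 202)
  expect_equal(c(floor(0.7 * 1006), floor(0.1 * 1006),
                 1006 - floor(0.7 * 1006) - floor(0.1 * 1006)),
               c(704, 100, 202))
  ## date-interval orderings
  d <- sampleDates(s); sp <- sampleSplits(s)
  expect_lt(max(d[sp == "train"]), min(d[sp == "val"]))
  expect_lt(max(d[sp == "val"]), min(d[sp == "test"]))
  ## degenerate: too few samples for a non-empty validation split
  x2 <- make_grids(matrix(250, 1, 9), matrix(8, 1, 9), matrix(2, 1, 9))
  expect_error(splitChronological(buildSamples(x2)),
               class = "invalidArgumentError")
  expect_error(splitChronological(s, fractions = c(0.5, 0.2, 0.2)),
               class = "invalidArgumentError")
})

test_that("IGBP classes aggregate to the four analysis groups", {
  expect_equal(aggregateLandcover(c(4, 5)), c("forest", "forest"))
  expect_equal(aggregateLandcover(c(9, 10)), c("grassland", "grassland"))
  expect_equal(aggregateLandcover(c(12, 14)), c("farmland", "farmland"))
  expect_equal(aggregateLandcover(c(13, 16)), c("non_study", "non_study"))
  ## classes the mapping does not assign go to non_study
  expect_equal(aggregateLandcover(1), "non_study")
  expect_error(aggregateLandcover(99), class = "mappingError")
})
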