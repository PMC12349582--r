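# Builds an importance table directly (no training) for the aggregation
# operations; sm values are arbitrary but fixed.
fake_importance <- function(sm, dates, grids = "g001",
                            landcover = "grassland",
                            lai = NULL, temperature = NULL) {
  n <- length(sm)
  data.frame(
    grid_id = rep_len(grids, n),
    landcover = rep_len(landcover, n),
    target_date = as.Date(rep_len(dates, n)),
    season = imvLAI:::seasonOf(as.Date(rep_len(dates, n))),
    sm_importance = sm,
    temp_importance = 1 - sm,
    lai = if (is.null(lai)) rep(1, n) else lai,
    soil_moisture = rep(250, n),
    temperature = if (is.null(temperature)) rep(10, n) else temperature)
}

test_that("extracted importance lies in [0,1] with exact complementarity", {
  s <- tiny_dataset(seed = 8)
  fit <- fitModel(initModel("imv", hidden = 4, seed = 1),
                  subsetSamples(s, split = "train"),
                  subsetSamples(s, split = "val"),
                  trainConfig(batch_size = 64, epochs = 5, seed = 1))
  imp <- extractImportance(fit, s)
  expect_equal(nrow(imp), length(subsetSamples(s, split = "test")))
  expect_true(all(imp$sm_importance >= 0 & imp$sm_importance <= 1))
  expect_identical(imp$temp_importance, 1 - imp$sm_importance)
  ## attention record integrity is enforced
  expect_error(imvLAI:::checkAttentionRecord(matrix(c(0.6, 0.6), 2, 1),
                                             c(0.5, 0.5)),
               class = "integrityError")
  expect_error(imvLAI:::checkAttentionRecord(matrix(c(0.4, 0.6), 2, 1),
                                             c(0.7, 0.6)),
               class = "integrityError")
})

test_that("dominance labelling applies the 0.5 threshold with ties to temperature", {
  d <- as.Date("2005-07-04")
  imp <- fake_importance(c(0.5, 0.5), d, grids = "g001")
  dm <- dominanceMap(imp)
  expect_equal(dm$grids$dominant, "temperature")  # tie -> temperature
  imp2 <- fake_importance(rep(0.8, 6), d,
                          grids = rep(c("g001", "g002", "g003"), 2))
  dm2 <- dominanceMap(imp2)
  expect_equal(unname(dm2$fractions["moisture"]), 1)
  expect_error(dominanceMap(imp, months = 1), class = "invalidArgumentError")
})

test_that("dominance fractions match a brute-force count on random grids", {
  set.seed(2)
  n_grids <- 10
  imp <- fake_importance(runif(n_grids * 8),
                         rep(as.Date("2010-06-10"), n_grids * 8),
                         grids = rep(sprintf("g%03d", 1:n_grids), each = 8))
  dm <- dominanceMap(imp)
  brute <- sapply(sprintf("g%03d", 1:n_grids), function(g) {
    mean(imp$sm_importance[imp$grid_id == g]) > 0.5
  })
  expect_equal(unname(dm$fractions["moisture"]), mean(brute))
  expect_equal(sum(dm$fractions), 1)
})

test_that("seasonal binning partitions the samples by month", {
  dates <- seq(as.Date("2010-01-05"), as.Date("2010-12-30"), by = "16 day")
  imp <- fake_importance(runif(length(dates)), dates)
  seas <- seasonalAggregate(imp)
  expect_named(seas, c("spring", "summer", "autumn", "winter"))
  ## March is spring; December and February share the winter bin
  expect_true(3 %in% unique(as.integer(format(
    imp$target_date[imp$season == "spring"], "%m"))))
  expect_setequal(unique(as.integer(format(
    imp$target_date[imp$season == "winter"], "%m"))), c(1, 2, 12))
  ## counts per season sum to the total
  counts <- table(imp$season)
  expect_equal(sum(counts), nrow(imp))
})

test_that("importance-vs-LAI bins reproduce brute-force means and mirror symmetry", {
  set.seed(3)
  n <- 300
  lai <- runif(n, 0, 6)
  sm <- plogis((lai - 3))  # importance rising with LAI
  imp <- fake_importance(sm, rep(as.Date("2011-06-02"), n), lai = lai)
  curves <- importanceVsLai(imp, n_bins = 10)
  ## brute-force oracle on the same equal-width bins
  edges <- seq(min(lai), max(lai), length.out = 11)
  bin <- pmin(findInterval(lai, edges, rightmost.closed = TRUE), 10)
  for (b in c(1, 5, 10)) {
    expect_equal(curves$sm_importance[b], mean(sm[bin == b]))
  }
  ## complement rule everywhere downstream
  expect_equal(curves$temp_importance, 1 - curves$sm_importance)
  ## constant importance gives flat curves at 0.5
  impc <- fake_importance(rep(0.5, n), rep(as.Date("2011-06-02"), n),
                          lai = lai)
  cc <- importanceVsLai(impc, n_bins = 5)
  expect_true(all(cc$sm_importance[cc$n > 0] == 0.5))
  ## empty bins are recorded as missing
  lai2 <- c(runif(50, 0, 1), runif(50, 5, 6))
  imp2 <- fake_importance(runif(100), rep(as.Date("2011-06-02"), 100),
                          lai = lai2)
  c2 <- importanceVsLai(imp2, n_bins = 10)
  expect_true(any(c2$n == 0 & is.na(c2$sm_importance)))
})

test_that("driver curves locate a constructed crossing point", {
  n <- 2000
  temperature <- seq(-10, 30, length.out = n)
  ## temperature importance falls linearly through 0.5 at exactly 18 degC
  temp_imp <- 0.5 - (temperature - 18) / 80
  imp <- fake_importance(1 - temp_imp, rep(as.Date("2012-07-03"), n),
                         temperature = temperature)
  out <- importanceVsDriver(imp, "temperature", n_bins = 20)
  expect_false(out$degenerate)
  expect_lt(abs(out$crossing - 18), diff(range(temperature)) / 20)
  ## bin means match a brute-force oracle
  edges <- seq(min(temperature), max(temperature), length.out = 21)
  bin <- pmin(findInterval(temperature, edges, rightmost.closed = TRUE), 20)
  for (b in c(2, 11, 19)) {
    expect_equal(out$curve$sm_importance[b], mean((1 - temp_imp)[bin == b]))
  }
  ## constant 0.5 is flagged degenerate with the crossing at the first edge
  impc <- fake_importance(rep(0.5, n), rep(as.Date("2012-07-03"), n),
                          temperature = temperature)
  outc <- importanceVsDriver(impc, "temperature", n_bins = 20)
  expect_true(outc$degenerate)
  expect_equal(outc$crossing, outc$curve$lo[1])
  ## monotone curves that never reach 0.5 report no crossing
  impm <- fake_importance(rep(0.2, n), rep(as.Date("2012-07-03"), n),
                          temperature = temperature)
  expect_true(is.na(importanceVsDriver(impm, "temperature")$crossing))
})

test_that("annual peak counting ignores sub-prominence wiggles", {
  cal <- compositeCalendar(2015, 1)
  unimodal <- exp(-((cal$doy - 200) / 50)^2)
  expect_equal(countAnnualPeaks(cal$date, unimodal)$n_peaks, 1L)
  bimodal <- exp(-((cal$doy - 130) / 25)^2) + exp(-((cal$doy - 240) / 25)^2)
  expect_equal(countAnnualPeaks(cal$date, bimodal)$n_peaks, 2L)
  ## a tiny wiggle on a shoulder does not count as a peak
  wiggly <- unimodal + 0.02 * sin(cal$doy / 3)
  expect_equal(countAnnualPeaks(cal$date, wiggly)$n_peaks, 1L)
  ## incomplete years are dropped
  expect_null(countAnnualPeaks(cal$date[1:20], unimodal[1:20]))
})
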