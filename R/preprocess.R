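#' Fixed physical normalization ranges
#'
#' The variables are normalized over fixed physical ranges rather than
#' data-driven ones: soil moisture 0-1000 kg/m2, temperature -50 to 50
#' deg C, LAI 0-10 m2/m2.
#'
#' @return data.frame with columns `variable`, `min`, `max`, `unit`.
#' @export
variableRanges <- function() {
  data.frame(
    variable = c("soil_moisture", "temperature", "lai"),
    min = c(0, -50, 0),
    max = c(1000, 50, 10),
    unit = c("kg/m2", "degC", "m2/m2"),
    stringsAsFactors = FALSE
  )
}

.rangeOf <- function(variable, ranges = variableRanges()) {
  i <- match(variable, ranges$variable)
  if (is.na(i)) imvStop(paste("unknown variable:", variable),
                        "invalidArgumentError")
  c(ranges$min[i], ranges$max[i])
}

#' Aggregate sub-daily readings to daily means
#'
#' @param dates calendar date (`Date`) of each reading.
#' @param values readings (same length as `dates`).
#' @return data.frame with `date` and `value` (daily arithmetic mean),
#'   one row per day from the first to the last date.
#' @export
aggregateDaily <- function(dates, values) {
  if (length(dates) != length(values) || length(dates) == 0L)
    imvStop("dates and values must be non-empty and equal length",
            "invalidArgumentError")
  dates <- as.Date(dates)
  full <- seq(min(dates), max(dates), by = "day")
  missing <- setdiff(as.character(full), as.character(unique(dates)))
  if (length(missing))
    imvStop(paste("no readings for day", missing[1]), "missingDataError")
  agg <- tapply(values, as.character(dates), mean)
  data.frame(date = as.Date(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Resample a daily series onto the 8-day composite calendar
#'
#' Each composite takes the mean of the daily values within its date span
#' (8 days, or 5-6 for the final composite of a year).
#'
#' @param daily data.frame with `date` and `value` (e.g. from
#'   [aggregateDaily()]).
#' @param calendar composite calendar from [compositeCalendar()].
#' @return numeric vector, one value per composite.
#' @export
resampleToComposites <- function(daily, calendar) {
  dd <- as.Date(daily$date)
  vapply(seq_len(nrow(calendar)), function(i) {
    span <- calendar$date[i] + seq_len(calendar$n_days[i]) - 1L
    j <- match(span, dd)
    if (anyNA(j))
      imvStop(sprintf("daily series does not cover composite %d (%s)",
                      calendar$index[i], calendar$date[i]),
              "missingDataError")
    mean(daily$value[j])
  }, numeric(1))
}

#' Keep grids with a valid LAI signal
#'
#' A grid is kept when its time-mean LAI is at or above `threshold`
#' (m2/m2) and none of the three variables has missing values; grids whose
#' whole-series mean LAI falls below the threshold are treated as
#' non-vegetated noise and excluded.
#'
#' @param x a [LaiGrids-class].
#' @param threshold validity threshold on time-mean LAI (default 0.1).
#' @return logical mask named by grid id (`TRUE` = keep); subset with
#'   `x[filterValidGrids(x), ]`.
#' @export
filterValidGrids <- function(x, threshold = 0.1) {
  if (ncol(x) == 0L)
    imvStop("empty series: no composites", "invalidArgumentError")
  complete <- !(rowSums(is.na(soilMoisture(x))) > 0 |
                  rowSums(is.na(airTemperature(x))) > 0 |
                  rowSums(is.na(leafAreaIndex(x))) > 0)
  meanLai <- rowMeans(leafAreaIndex(x))
  stats::setNames(complete & meanLai >= threshold, rownames(x))
}

#' Min-max normalize to the unit interval
#'
#' `x' = (x - min) / (max - min)` over the variable's fixed physical range.
#' Values outside the declared range raise a range-violation error naming
#' the variable and the first offending index (the ranges are hard bounds;
#' clipping would mask upstream bugs).
#'
#' @param x numeric values (vector, matrix or array).
#' @param variable one of `"soil_moisture"`, `"temperature"`, `"lai"`.
#' @param ranges range table, see [variableRanges()].
#' @return values mapped to `[0, 1]`, same shape as `x`.
#' @export
normalizeValues <- function(x, variable, ranges = variableRanges()) {
  r <- .rangeOf(variable, ranges)
  bad <- which(x < r[1] | x > r[2])
  if (length(bad))
    imvStop(sprintf("%s value %g at index %d outside [%g, %g]",
                    variable, x[bad[1]], bad[1], r[1], r[2]),
            "rangeViolationError")
  (x - r[1]) / (r[2] - r[1])
}

#' @rdname normalizeValues
#' @export
denormalizeValues <- function(x, variable, ranges = variableRanges()) {
  r <- .rangeOf(variable, ranges)
  x * (r[2] - r[1]) + r[1]
}

#' Aggregate IGBP land-cover classes to analysis groups
#'
#' Maps the 17-class IGBP scheme onto the four analysis groups: forest
#' (deciduous broadleaf, mixed forests), grassland (woody savannas,
#' savannas, grasslands), farmland (croplands and cropland/natural-
#' vegetation mosaics) and non_study (urban, barren and every class not
#' otherwise mapped). The mapping ships as an editable CSV
#' (`system.file("extdata", "igbp_landcover_map.csv", package = "imvLAI")`).
#'
#' @param codes integer IGBP class codes (1-17).
#' @param map optional replacement mapping data.frame with columns `code`,
#'   `igbp_class`, `group`.
#' @return character vector of group labels.
#' @export
aggregateLandcover <- function(codes, map = NULL) {
  if (is.null(map)) {
    map <- utils::read.csv(system.file("extdata", "igbp_landcover_map.csv",
                                       package = "imvLAI"))
  }
  i <- match(as.integer(codes), map$code)
  if (anyNA(i))
    imvStop(sprintf("unknown IGBP class code: %s",
                    codes[which(is.na(i))[1]]), "mappingError")
  as.character(map$group[i])
}
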