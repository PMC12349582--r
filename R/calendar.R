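#' 8-day composite calendar
#'
#' Builds the MODIS-style 8-day composite calendar: 46 composites per
#' calendar year starting at day-of-year 1, 9, ..., 361. Composites span
#' 8 days except the last of each year, which absorbs the 5-day (6 in
#' leap years) remainder.
#'
#' @param start_year first calendar year (e.g. 2000).
#' @param years number of years covered (>= 1).
#' @return A `data.frame` with one row per composite and columns
#'   `index`, `year`, `doy` (day of year of the composite start),
#'   `date` (`Date` of the composite start) and `n_days` (days spanned).
#' @examples
#' cal <- compositeCalendar(2000, 22)
#' nrow(cal)  # 1012 composites over 2000-2021
#' @export
compositeCalendar <- function(start_year, years) {
  years <- assertCount(years, "years")
  start_year <- assertCount(start_year, "start_year", min = 1L)
  doy <- seq(1L, 361L, by = 8L)
  out <- do.call(rbind, lapply(seq_len(years) - 1L, function(k) {
    yr <- start_year + k
    ndays_year <- if ((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0) 366L else 365L
    data.frame(
      year = yr,
      doy = doy,
      date = as.Date(doy - 1L, origin = as.Date(sprintf("%d-01-01", yr))),
      n_days = c(rep(8L, 45L), ndays_year - 360L)
    )
  }))
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Days spanned by a sliding input window
#'
#' @param window number of consecutive composites in the window.
#' @param resolution composite length in days (8 for the MODIS calendar).
#' @return Window span in days (e.g. 7 composites at 8 days = 56 days).
#' @export
windowSpanDays <- function(window = 7L, resolution = 8L) {
  assertCount(window, "window") * assertCount(resolution, "resolution")
}

## Meteorological season of a composite date: MAM/JJA/SON/DJF.
seasonOf <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  factor(
    c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
      "summer", "autumn", "autumn", "autumn", "winter")[m],
    levels = c("spring", "summer", "autumn", "winter")
  )
}
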