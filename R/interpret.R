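#' Per-sample soil-moisture importance from attention records
#'
#' The variable-attention weight Pr(z = soil moisture) of each test sample
#' is taken as the soil-moisture importance; temperature importance is its
#' complement (1 - sm). Alongside the importance, the returned table
#' carries the denormalized target LAI and the denormalized soil moisture
#' and temperature at the window's final step, so downstream binning by
#' LAI phase or by driver value needs no further lookups.
#'
#' @param fits named list of per-grid [LaiFit-class] objects with family
#'   `"imv"`, or a single fit used for every grid.
#' @param samples split-tagged [LaiSamples-class].
#' @param split which split to extract from (default `"test"`, avoiding
#'   training leakage into the interpretation).
#' @return data.frame with `grid_id`, `landcover`, `target_date`, `season`,
#'   `sm_importance`, `temp_importance`, `lai`, `soil_moisture`,
#'   `temperature`.
#' @export
extractImportance <- function(fits, samples, split = "test") {
  gids <- unique(sampleGrids(samples))
  single <- is(fits, "LaiFit")
  rows <- lapply(gids, function(g) {
    ss <- subsetSamples(samples, split = split, grid = g)
    fit <- if (single) fits else fits[[g]]
    rec <- attentionRecords(bestModel(fit), ss)
    for (i in seq_len(nrow(rec$variable))) {
      checkAttentionRecord(matrix(rec$temporal[i, , ], dim(rec$temporal)[2]),
                           rec$variable[i, ])
    }
    w <- dim(sampleInputs(ss))[2]
    sm <- rec$variable[, 1L]
    data.frame(
      grid_id = g,
      landcover = sampleLandcover(ss),
      target_date = sampleDates(ss),
      season = seasonOf(sampleDates(ss)),
      sm_importance = sm,
      temp_importance = 1 - sm,
      lai = denormalizeValues(sampleTargets(ss), "lai"),
      soil_moisture = denormalizeValues(sampleInputs(ss)[, w, 1L],
                                        "soil_moisture"),
      temperature = denormalizeValues(sampleInputs(ss)[, w, 2L],
                                      "temperature"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominance map over a period
#'
#' Averages each grid's soil-moisture importance over the (optionally
#' filtered) samples and labels the grid moisture-dominant when the mean
#' exceeds 0.5, temperature-dominant otherwise (a tie at exactly 0.5 is
#' temperature-dominant).
#'
#' @param importance table from [extractImportance()].
#' @param months optional integer months (1-12) restricting the period.
#' @return list with `grids` (data.frame: `grid_id`, `landcover`,
#'   `mean_sm_importance`, `dominant`) and `fractions` (named fractions of
#'   moisture- vs temperature-dominant grids, summing to 1).
#' @export
dominanceMap <- function(importance, months = NULL) {
  x <- importance
  if (!is.null(months))
    x <- x[as.integer(format(x$target_date, "%m")) %in% months, ]
  if (nrow(x) == 0L)
    imvStop("no samples in the requested period", "invalidArgumentError")
  agg <- stats::aggregate(list(mean_sm_importance = x$sm_importance),
                          by = list(grid_id = x$grid_id), mean)
  lc <- x$landcover[match(agg$grid_id, x$grid_id)]
  agg$landcover <- lc
  agg$dominant <- ifelse(agg$mean_sm_importance > 0.5,
                         "moisture", "temperature")
  fr <- c(moisture = mean(agg$dominant == "moisture"),
          temperature = mean(agg$dominant == "temperature"))
  list(grids = agg[c("grid_id", "landcover", "mean_sm_importance",
                     "dominant")],
       fractions = fr)
}

#' Seasonal dominance maps
#'
#' Bins samples by target-date month into spring (March-May), summer
#' (June-August), autumn (September-November) and winter
#' (December-February) and builds a [dominanceMap()] per season.
#'
#' @param importance table from [extractImportance()].
#' @return named list of dominance maps (`spring`, `summer`, `autumn`,
#'   `winter`); a season with no samples is `NULL`.
#' @export
seasonalAggregate <- function(importance) {
  bins <- list(spring = 3:5, summer = 6:8, autumn = 9:11,
               winter = c(12L, 1L, 2L))
  lapply(bins, function(m) {
    has <- any(as.integer(format(importance$target_date, "%m")) %in% m)
    if (!has) NULL else dominanceMap(importance, months = m)
  })
}

## Shared equal-width binning of `by` within groups; returns per-bin mean
## importance. Empty bins are kept with n = 0 and NA means.
.binImportance <- function(x, by, n_bins, group_cols) {
  groups <- if (length(group_cols)) {
    interaction(x[group_cols], drop = TRUE, sep = "|")
  } else factor(rep("all", nrow(x)))
  out <- lapply(levels(groups), function(gl) {
    xi <- x[groups == gl, ]
    r <- range(xi[[by]])
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    edges <- seq(r[1], r[2], length.out = n_bins + 1L)
    bin <- pmin(findInterval(xi[[by]], edges, rightmost.closed = TRUE),
                n_bins)
    res <- data.frame(group = gl, bin = seq_len(n_bins),
                      lo = edges[-length(edges)], hi = edges[-1L])
    res$mid <- (res$lo + res$hi) / 2
    res$sm_importance <- vapply(seq_len(n_bins), function(b) {
      v <- xi$sm_importance[bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    res$temp_importance <- 1 - res$sm_importance
    res$n <- as.integer(tabulate(bin, n_bins))
    res
  })
  out <- do.call(rbind, out)
  if (length(group_cols)) {
    parts <- do.call(rbind, strsplit(as.character(out$group), "|",
                                     fixed = TRUE))
    colnames(parts) <- group_cols
    out <- cbind(as.data.frame(parts), out[setdiff(names(out), "group")])
  } else {
    out$group <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Importance as a function of LAI phase
#'
#' Bins samples into equal-width LAI bins (per vegetation class, and
#' optionally per season) and averages the importance within each bin,
#' tracing how driver importance shifts along the canopy development
#' cycle.
#'
#' @param importance table from [extractImportance()].
#' @param n_bins number of equal-width LAI bins (default 20).
#' @param by grouping columns (default `"landcover"`; add `"season"` for
#'   season-resolved curves).
#' @return data.frame of per-bin mean `sm_importance` and its complement
#'   `temp_importance`, with bin edges/midpoints and counts; empty bins are
#'   recorded with `n = 0` and `NA` means.
#' @export
importanceVsLai <- function(importance, n_bins = 20L, by = "landcover") {
  .binImportance(importance, "lai", assertCount(n_bins, "n_bins"), by)
}

#' Importance as a function of a driver value
#'
#' Bins samples by the driver value at the target step and averages
#' importance per bin; also locates the crossing point where temperature
#' and soil-moisture importance become equivalent (temperature importance
#' crosses 0.5), by linear interpolation between the bin midpoints around
#' the first sign change.
#'
#' @param importance table from [extractImportance()].
#' @param driver `"temperature"` or `"soil_moisture"`.
#' @param n_bins number of equal-width driver bins (default 20).
#' @param by optional grouping columns (default none: one pooled curve).
#' @return list with `curve` (per-bin means), `crossing` (driver value, or
#'   `NA` when the curves never cross) and `degenerate` (`TRUE` when the
#'   curves sit at 0.5 everywhere, in which case the crossing is reported
#'   at the first bin edge).
#' @export
importanceVsDriver <- function(importance, driver = c("temperature",
                                                      "soil_moisture"),
                               n_bins = 20L, by = character()) {
  driver <- match.arg(driver)
  curve <- .binImportance(importance, driver,
                          assertCount(n_bins, "n_bins"), by)
  cc <- curve[!is.na(curve$sm_importance), ]
  dlt <- cc$temp_importance - 0.5
  degenerate <- nrow(cc) > 0 && all(abs(dlt) < 1e-9)
  crossing <- NA_real_
  if (degenerate) {
    crossing <- curve$lo[1]
  } else if (nrow(cc) >= 2) {
    sgn <- sign(dlt)
    flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                    (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
    if (length(which(dlt == 0))) {
      crossing <- cc$mid[which(dlt == 0)[1]]
    } else if (length(flip)) {
      i <- flip[1]
      crossing <- cc$mid[i] + (0 - dlt[i]) *
        (cc$mid[i + 1] - cc$mid[i]) / (dlt[i + 1] - dlt[i])
    }
  }
  list(curve = curve, crossing = crossing, degenerate = degenerate)
}

#' Count intra-annual peaks of an LAI trajectory
#'
#' Counts local maxima per calendar year, ignoring minor wiggles: a peak
#' only counts when it rises at least `min_prominence` times the year's
#' value range above the valley separating it from every already accepted
#' (higher) peak.
#'
#' @param dates composite dates of the series.
#' @param values LAI values (observed or predicted).
#' @param min_prominence fraction of the annual range a peak must stand
#'   out by (default 0.2).
#' @param complete_years_only drop years not fully covered by the
#'   composite calendar (fewer than 46 composites).
#' @return data.frame with `year` and `n_peaks`.
#' @export
countAnnualPeaks <- function(dates, values, min_prominence = 0.2,
                             complete_years_only = TRUE) {
  yr <- as.integer(format(as.Date(dates), "%Y"))
  out <- lapply(unique(yr), function(y) {
    v <- values[yr == y]
    if (complete_years_only && length(v) < 46L) return(NULL)
    rng <- diff(range(v))
    if (rng == 0) return(data.frame(year = y, n_peaks = 0L))
    ## candidate local maxima (plateau-safe via run-length collapse)
    r <- rle(v)
    vv <- r$values
    ends <- cumsum(r$lengths)
    k <- length(vv)
    if (k < 3L) return(data.frame(year = y, n_peaks = 1L))
    cand <- which(vv > c(-Inf, vv[-k]) & vv > c(vv[-1], -Inf))
    cand <- cand[order(vv[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in cand) {
      ok <- TRUE
      for (j in kept) {
        valley <- min(vv[min(i, j):max(i, j)])
        if (min(vv[i], vv[j]) - valley < min_prominence * rng) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    data.frame(year = y, n_peaks = length(kept))
  })
  do.call(rbind, out)
}
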