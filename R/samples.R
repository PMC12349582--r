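#' Build sliding-window samples from gridded series
#'
#' Normalizes the three variables over their fixed physical ranges and
#' slides a window of `window` consecutive composites one step at a time
#' along each grid's series. Each sample's inputs are the window's
#' normalized soil-moisture and temperature values (window x 2); the target
#' is the normalized LAI at the window's final step. A series of length `T`
#' yields `T - window + 1` samples per grid.
#'
#' @param x a [LaiGrids-class].
#' @param window window length in composites (default 7, i.e. 56 days).
#' @return A [LaiSamples-class] with all samples tagged `unassigned`.
#' @export
buildSamples <- function(x, window = 7L) {
  window <- assertCount(window, "window")
  nt <- ncol(x)
  if (nt < window)
    imvStop(sprintf("series length %d is shorter than the window (%d)",
                    nt, window), "insufficientDataError")
  sm <- normalizeValues(soilMoisture(x), "soil_moisture")
  ta <- normalizeValues(airTemperature(x), "temperature")
  la <- normalizeValues(leafAreaIndex(x), "lai")
  dates <- compositeDates(x)
  lc <- landcover(x)

  nper <- nt - window + 1L
  ng <- nrow(x)
  n <- ng * nper
  inputs <- array(NA_real_, c(n, window, 2L),
                  dimnames = list(NULL, NULL, c("soil_moisture", "temperature")))
  targets <- numeric(n)
  tdates <- rep(dates[window:nt], ng)
  grids <- rep(rownames(x), each = nper)
  for (g in seq_len(ng)) {
    idx <- (g - 1L) * nper + seq_len(nper)
    for (w in seq_len(window)) {
      inputs[idx, w, 1L] <- sm[g, w:(w + nper - 1L)]
      inputs[idx, w, 2L] <- ta[g, w:(w + nper - 1L)]
    }
    targets[idx] <- la[g, window:nt]
  }
  new("LaiSamples",
      inputs = inputs, targets = targets, dates = tdates, grids = grids,
      landcoverLabels = as.character(lc[grids]),
      split = factor(rep("unassigned", n),
                     levels = c("train", "val", "test", "unassigned")),
      window = window, ranges = variableRanges())
}

#' Chronological train/validation/test split
#'
#' Within each grid, the first `floor(f_train * n)` samples (by target
#' date) become training data, the next `floor(f_val * n)` validation data
#' and the remainder test data, so all training dates precede all
#' validation dates, which precede all test dates.
#'
#' @param samples a [LaiSamples-class].
#' @param fractions train/val/test fractions summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @return The samples with split tags assigned.
#' @export
splitChronological <- function(samples, fractions = c(0.7, 0.1, 0.2)) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0))
    imvStop("fractions must be three non-negative values summing to 1",
            "invalidArgumentError")
  split <- as.character(samples@split)
  for (g in unique(samples@grids)) {
    i <- which(samples@grids == g)
    i <- i[order(samples@dates[i])]
    n <- length(i)
    ntr <- floor(fractions[1] * n)
    nva <- floor(fractions[2] * n)
    nte <- n - ntr - nva
    if (ntr == 0L || nva == 0L || nte == 0L)
      imvStop(sprintf("grid %s: a split would be empty (n = %d)", g, n),
              "invalidArgumentError")
    split[i] <- rep(c("train", "val", "test"), c(ntr, nva, nte))
  }
  initialize(samples,
             split = factor(split,
                            levels = c("train", "val", "test", "unassigned")))
}

#' Subset samples by split and/or grid
#'
#' @param samples a [LaiSamples-class].
#' @param split optional split tag(s) to keep.
#' @param grid optional grid id(s) to keep.
#' @return the filtered [LaiSamples-class].
#' @export
subsetSamples <- function(samples, split = NULL, grid = NULL) {
  keep <- rep(TRUE, length(samples))
  if (!is.null(split)) keep <- keep & samples@split %in% split
  if (!is.null(grid)) keep <- keep & samples@grids %in% grid
  samples[which(keep)]
}
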