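#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot`. Undefined when the observations are
#' constant (zero total sum of squares).
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return scalar R2 (dimensionless; 1 for perfect prediction, 0 when
#'   predicting the observed mean, negative when worse).
#' @export
r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    imvStop("observed and predicted must have equal length >= 2",
            "invalidArgumentError")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    imvStop("R2 is undefined for constant observations",
            "undefinedMetricError")
  1 - sum((observed - predicted)^2) / sst
}

#' Root mean squared error
#'
#' @param observed,predicted numeric vectors of equal length (>= 1); for
#'   LAI these are in m2/m2 (denormalized).
#' @return scalar RMSE in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    imvStop("observed and predicted must have equal length >= 1",
            "invalidArgumentError")
  sqrt(mean((observed - predicted)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return scalar MAE in the units of the inputs.
#' @export
mae <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    imvStop("observed and predicted must have equal length >= 1",
            "invalidArgumentError")
  mean(abs(observed - predicted))
}

#' Per-grid test-split metrics
#'
#' Predicts each grid's test samples with its own fitted model,
#' denormalizes predictions and targets to m2/m2 and computes R2, RMSE and
#' MAE. R2 is `NA` for grids with constant observed LAI (they are kept for
#' RMSE/MAE).
#'
#' @param fits named list of per-grid [LaiFit-class] objects (e.g.
#'   `pretrainFinetune(...)$grids`), or a single fit applied to every grid.
#' @param samples the split-tagged [LaiSamples-class].
#' @param split which split to evaluate (default `"test"`).
#' @return data.frame with `grid_id`, `landcover`, `r2`, `rmse`, `mae`, `n`.
#' @export
evaluateGrids <- function(fits, samples, split = "test") {
  gids <- unique(sampleGrids(samples))
  single <- is(fits, "LaiFit")
  rows <- lapply(gids, function(g) {
    ss <- subsetSamples(samples, split = split, grid = g)
    fit <- if (single) fits else fits[[g]]
    pred <- predictLai(bestModel(fit), ss, denormalize = TRUE)
    obs <- denormalizeValues(sampleTargets(ss), "lai")
    data.frame(
      grid_id = g,
      landcover = sampleLandcover(ss)[1],
      r2 = if (stats::sd(obs) > 0) r2(obs, pred) else NA_real_,
      rmse = rmse(obs, pred),
      mae = mae(obs, pred),
      n = length(obs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vegetation-class summary of per-grid metrics
#'
#' @param metrics per-grid metric table from [evaluateGrids()].
#' @return data.frame with per-class mean and standard deviation of each
#'   metric and the number of grids; classes without any grid are omitted
#'   with a warning.
#' @export
summarizeByVegetation <- function(metrics) {
  if (is.factor(metrics$landcover)) {
    empty <- setdiff(levels(metrics$landcover), unique(metrics$landcover))
    if (length(empty))
      warning("omitting empty vegetation class(es): ",
              paste(empty, collapse = ", "))
    metrics$landcover <- as.character(metrics$landcover)
  }
  agg <- function(f) stats::aggregate(
    metrics[c("r2", "rmse", "mae")], by = list(landcover = metrics$landcover),
    FUN = function(x) f(x[!is.na(x)]))
  m <- agg(mean); s <- agg(function(x) if (length(x) > 1) stats::sd(x) else 0)
  cnt <- stats::aggregate(list(n_grids = metrics$grid_id),
                          by = list(landcover = metrics$landcover), length)
  out <- data.frame(
    landcover = m$landcover,
    r2_mean = m$r2, r2_sd = s$r2,
    rmse_mean = m$rmse, rmse_sd = s$rmse,
    mae_mean = m$mae, mae_sd = s$mae,
    n_grids = cnt$n_grids)
  out
}
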