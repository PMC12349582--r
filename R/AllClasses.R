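#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.LANDCOVER_LEVELS <- c("forest", "grassland", "crop_single", "crop_double",
                       "non_vegetated")

#' Grid layout and land-cover specification
#'
#' Describes a rectangular grid of cells, each carrying exactly one
#' vegetation label used by the synthetic generator.
#'
#' @slot nRows,nCols grid dimensions.
#' @slot gridIds unique cell identifiers (length nRows * nCols).
#' @slot landcover per-cell label, one of forest, grassland, crop_single,
#'   crop_double, non_vegetated.
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer",
                 gridIds = "character", landcover = "character"),
  validity = function(object) {
    n <- object@nRows * object@nCols
    if (length(object@gridIds) != n) return("gridIds length != nRows * nCols")
    if (anyDuplicated(object@gridIds)) return("gridIds must be unique")
    if (length(object@landcover) != n) return("landcover length != nRows * nCols")
    bad <- setdiff(unique(object@landcover), .LANDCOVER_LEVELS)
    if (length(bad)) return(paste("unknown landcover label:", bad[1]))
    TRUE
  }
)

#' Construct a GridSpec
#'
#' @param n_rows,n_cols grid dimensions.
#' @param landcover optional per-cell labels (row-major). When omitted the
#'   five labels are cycled across cells so every class is represented.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(2, 2, landcover = c("forest", "grassland", "crop_double", "non_vegetated"))
#' @export
gridSpec <- function(n_rows, n_cols, landcover = NULL) {
  n_rows <- assertCount(n_rows, "n_rows")
  n_cols <- assertCount(n_cols, "n_cols")
  n <- n_rows * n_cols
  if (is.null(landcover)) {
    landcover <- rep_len(.LANDCOVER_LEVELS, n)
  }
  new("GridSpec", nRows = n_rows, nCols = n_cols,
      gridIds = sprintf("g%03d", seq_len(n)),
      landcover = as.character(landcover))
}

#' @describeIn GridSpec-class per-cell vegetation labels, named by grid id.
#' @param x a `GridSpec` or `LaiGrids` object.
#' @export
setGeneric("landcover", function(x) standardGeneric("landcover"))

#' @export
setMethod("landcover", "GridSpec", function(x) {
  stats::setNames(x@landcover, x@gridIds)
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells\n", object@nRows, object@nCols))
  print(table(object@landcover))
})

#' Synthetic hydrothermal coupling parameters
#'
#' Ground-truth parameters of the generator. `dominanceLambda` is the
#' fraction of the latent vegetation growth signal attributed to soil
#' moisture (the remainder to temperature); `lagSteps` is the number of
#' past composites (including the current one) whose mean forcing drives
#' LAI. Seasonal sinusoid amplitudes/phases, AR(1) persistence of soil
#' moisture, per-grid mean spread and additive noise levels define the
#' forcing statistics; `envelopes` holds per-vegetation phenology
#' (peak day-of-year, width in days, maximum LAI; two peaks for
#' double-season crops).
#'
#' @export
setClass("CouplingParams",
  representation(
    dominanceLambda = "numeric", lagSteps = "integer",
    noiseSdT = "numeric", noiseSdSM = "numeric", noiseSdLAI = "numeric",
    meanT = "numeric", ampT = "numeric", phaseT = "numeric", arT = "numeric",
    meanSM = "numeric", ampSM = "numeric", phaseSM = "numeric",
    arSM = "numeric", gridSdT = "numeric", gridSdSM = "numeric",
    satMid = "numeric", satScale = "numeric", envelopes = "list"
  ),
  validity = function(object) {
    if (object@dominanceLambda < 0 || object@dominanceLambda > 1)
      return("dominanceLambda must lie in [0, 1]")
    if (object@lagSteps < 1L) return("lagSteps must be >= 1")
    sds <- c(object@noiseSdT, object@noiseSdSM, object@noiseSdLAI,
             object@gridSdT, object@gridSdSM)
    if (any(sds < 0)) return("noise standard deviations must be >= 0")
    need <- setdiff(.LANDCOVER_LEVELS, names(object@envelopes))
    if (length(need)) return(paste("envelopes missing for:", need[1]))
    TRUE
  }
)

#' Construct CouplingParams
#'
#' Defaults describe a semi-arid temperate setting: mean temperature 8 deg C
#' with a 15 deg C seasonal amplitude peaking in late July and persistent
#' synoptic anomalies (AR(1), 0.6); mean 0-100 cm soil moisture 250 kg/m2
#' with a 50 kg/m2 seasonal cycle peaking in mid-September and strongly
#' persistent anomalies (AR(1), 0.9) of a size comparable to the seasonal
#' cycle, emulating episodic rainfall recharge. Both drivers thus carry
#' substantial variation independent of the shared seasonal cycle, which is
#' what makes the ground-truth dominance identifiable. Phenology is a
#' unimodal summer envelope (with a non-zero off-season floor) for
#' forest/grassland/single-season crops and a bimodal winter-wheat /
#' summer-maize envelope with a deep harvest dip for double-season crops.
#'
#' @param dominance_lambda fraction in `[0,1]`: weight of soil moisture (vs
#'   temperature) in the latent growth signal.
#' @param lag_steps composites of forcing history averaged into the growth
#'   signal (default 3, i.e. 24 days, inside the 56-day input window).
#' @param noise_sd_T,noise_sd_SM,noise_sd_LAI innovation sd of the driver
#'   anomalies (deg C, kg/m2) and additive LAI noise sd (m2/m2).
#' @param mean_T,amp_T,phase_T,ar_T temperature sinusoid mean, amplitude
#'   (deg C), phase (day of year of the upward zero crossing) and AR(1)
#'   persistence of anomalies.
#' @param mean_SM,amp_SM,phase_SM,ar_SM soil-moisture seasonal mean,
#'   amplitude, phase and AR(1) persistence of anomalies.
#' @param grid_sd_T,grid_sd_SM sd of static per-grid mean offsets.
#' @param sat_mid,sat_scale midpoint and scale of the logistic saturation
#'   mapping the latent growth signal to relative LAI.
#' @param envelopes named list of per-vegetation phenology parameters, each
#'   `list(peaks=, width=, lai_max=, floor=)`.
#' @return A [CouplingParams-class] object.
#' @export
couplingParams <- function(dominance_lambda = 0.5, lag_steps = 3L,
                           noise_sd_T = 1.5, noise_sd_SM = 20,
                           noise_sd_LAI = 0.15,
                           mean_T = 8, amp_T = 15, phase_T = 110, ar_T = 0.6,
                           mean_SM = 250, amp_SM = 50, phase_SM = 170,
                           ar_SM = 0.9, grid_sd_T = 1, grid_sd_SM = 20,
                           sat_mid = 0.5, sat_scale = 0.15,
                           envelopes = defaultEnvelopes()) {
  new("CouplingParams",
      dominanceLambda = dominance_lambda,
      lagSteps = assertCount(lag_steps, "lag_steps"),
      noiseSdT = noise_sd_T, noiseSdSM = noise_sd_SM, noiseSdLAI = noise_sd_LAI,
      meanT = mean_T, ampT = amp_T, phaseT = phase_T, arT = ar_T,
      meanSM = mean_SM, ampSM = amp_SM, phaseSM = phase_SM,
      arSM = ar_SM, gridSdT = grid_sd_T, gridSdSM = grid_sd_SM,
      satMid = sat_mid, satScale = sat_scale, envelopes = envelopes)
}

#' Default phenological envelopes per vegetation class
#'
#' @return Named list with `peaks` (day(s) of year), `width` (days),
#'   `lai_max` (m2/m2) and `floor` (off-season fraction of the envelope)
#'   per class.
#' @export
defaultEnvelopes <- function() {
  list(
    forest        = list(peaks = 200, width = 60, lai_max = 6.0, floor = 0.5),
    grassland     = list(peaks = 210, width = 50, lai_max = 3.5, floor = 0.4),
    crop_single   = list(peaks = 200, width = 45, lai_max = 5.0, floor = 0.3),
    crop_double   = list(peaks = c(130, 235), width = 28, lai_max = 5.0,
                         floor = 0.05),
    non_vegetated = list(peaks = 200, width = 80, lai_max = 0.03, floor = 0)
  )
}

#' Gridded soil-moisture / temperature / LAI series
#'
#' A [SummarizedExperiment::SummarizedExperiment] with grid cells as rows
#' and 8-day composites as columns, carrying assays `soil_moisture`
#' (kg/m2, 0-1000), `temperature` (deg C, -50 to 50) and `lai` (m2/m2,
#' 0-10). `rowData` holds grid id, row/col index and landcover label;
#' `colData` holds the composite calendar.
#'
#' @export
setClass("LaiGrids", contains = "SummarizedExperiment",
  validity = function(object) {
    need <- c("soil_moisture", "temperature", "lai")
    miss <- setdiff(need, SummarizedExperiment::assayNames(object))
    if (length(miss)) return(paste("missing assay:", miss[1]))
    cd <- colData(object)
    if (!all(c("date", "year", "doy") %in% colnames(cd)))
      return("colData must carry date, year, doy")
    if (ncol(object) > 1 && any(diff(as.Date(cd$date)) <= 0))
      return("composite dates must be strictly increasing")
    rng <- list(soil_moisture = c(0, 1000), temperature = c(-50, 50),
                lai = c(0, 10))
    for (v in need) {
      a <- assay(object, v)
      ok <- is.na(a) | (a >= rng[[v]][1] & a <= rng[[v]][2])
      if (!all(ok)) return(sprintf("assay '%s' outside its physical range", v))
    }
    TRUE
  }
)

#' @describeIn LaiGrids-class soil-moisture assay (grids x composites, kg/m2).
#' @param x a `LaiGrids` object.
#' @export
setGeneric("soilMoisture", function(x) standardGeneric("soilMoisture"))
#' @export
setMethod("soilMoisture", "LaiGrids", function(x) assay(x, "soil_moisture"))

#' @describeIn LaiGrids-class air-temperature assay (deg C).
#' @export
setGeneric("airTemperature", function(x) standardGeneric("airTemperature"))
#' @export
setMethod("airTemperature", "LaiGrids", function(x) assay(x, "temperature"))

#' @describeIn LaiGrids-class LAI assay (m2/m2).
#' @export
setGeneric("leafAreaIndex", function(x) standardGeneric("leafAreaIndex"))
#' @export
setMethod("leafAreaIndex", "LaiGrids", function(x) assay(x, "lai"))

#' @export
setMethod("landcover", "LaiGrids", function(x) {
  stats::setNames(as.character(rowData(x)$landcover), rownames(x))
})

#' @describeIn LaiGrids-class composite start dates (class `Date`).
#' @export
setGeneric("compositeDates", function(x) standardGeneric("compositeDates"))
#' @export
setMethod("compositeDates", "LaiGrids", function(x) as.Date(colData(x)$date))

setMethod("show", "LaiGrids", function(object) {
  cat(sprintf("LaiGrids: %d grid cells x %d composites (%s .. %s)\n",
              nrow(object), ncol(object),
              min(compositeDates(object)), max(compositeDates(object))))
  print(table(landcover(object)))
})

#' Windowed regression samples
#'
#' Holds the sliding-window samples of one or more grids: a
#' `n x window x 2` array of min-max normalized inputs (soil moisture,
#' temperature), the normalized LAI target at each window's final step,
#' target dates, grid ids, vegetation labels and chronological split tags.
#'
#' @export
setClass("LaiSamples",
  representation(inputs = "array", targets = "numeric", dates = "Date",
                 grids = "character", landcoverLabels = "character",
                 split = "factor", window = "integer", ranges = "data.frame"),
  validity = function(object) {
    n <- length(object@targets)
    d <- dim(object@inputs)
    if (length(d) != 3L || d[1] != n || d[2] != object@window || d[3] != 2L)
      return("inputs must be an n x window x 2 array")
    if (length(object@dates) != n || length(object@grids) != n ||
        length(object@split) != n || length(object@landcoverLabels) != n)
      return("per-sample metadata lengths differ")
    vals <- c(object@inputs, object@targets)
    if (any(vals < -1e-9 | vals > 1 + 1e-9, na.rm = TRUE))
      return("normalized values must lie in [0, 1]")
    if (!all(levels(object@split) == c("train", "val", "test", "unassigned")))
      return("split levels must be train/val/test/unassigned")
    for (g in unique(object@grids)) {
      i <- object@grids == g
      if (any(diff(object@dates[i]) <= 0))
        return("target dates must be strictly increasing within a grid")
      s <- object@split[i]; dt <- object@dates[i]
      for (pair in list(c("train", "val"), c("val", "test"), c("train", "test"))) {
        a <- dt[s == pair[1]]; b <- dt[s == pair[2]]
        if (length(a) && length(b) && max(a) >= min(b))
          return(sprintf("%s dates must precede %s dates", pair[1], pair[2]))
      }
    }
    TRUE
  }
)

#' @describeIn LaiSamples-class normalized input array (n x window x 2;
#'   variable order soil_moisture, temperature).
#' @param x a `LaiSamples` object.
#' @export
setGeneric("sampleInputs", function(x) standardGeneric("sampleInputs"))
#' @export
setMethod("sampleInputs", "LaiSamples", function(x) x@inputs)

#' @describeIn LaiSamples-class normalized LAI targets.
#' @export
setGeneric("sampleTargets", function(x) standardGeneric("sampleTargets"))
#' @export
setMethod("sampleTargets", "LaiSamples", function(x) x@targets)

#' @describeIn LaiSamples-class target composite dates.
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))
#' @export
setMethod("sampleDates", "LaiSamples", function(x) x@dates)

#' @describeIn LaiSamples-class grid id of each sample.
#' @export
setGeneric("sampleGrids", function(x) standardGeneric("sampleGrids"))
#' @export
setMethod("sampleGrids", "LaiSamples", function(x) x@grids)

#' @describeIn LaiSamples-class chronological split tag of each sample.
#' @export
setGeneric("sampleSplits", function(x) standardGeneric("sampleSplits"))
#' @export
setMethod("sampleSplits", "LaiSamples", function(x) x@split)

#' @describeIn LaiSamples-class vegetation label of each sample.
#' @export
setGeneric("sampleLandcover", function(x) standardGeneric("sampleLandcover"))
#' @export
setMethod("sampleLandcover", "LaiSamples", function(x) x@landcoverLabels)

#' @export
setMethod("length", "LaiSamples", function(x) length(x@targets))

#' @export
setMethod("[", signature("LaiSamples", "ANY", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    initialize(x,
      inputs = x@inputs[i, , , drop = FALSE], targets = x@targets[i],
      dates = x@dates[i], grids = x@grids[i],
      landcoverLabels = x@landcoverLabels[i], split = x@split[i])
  })

setMethod("show", "LaiSamples", function(object) {
  cat(sprintf("LaiSamples: %d samples, window %d, %d grids\n",
              length(object), object@window, length(unique(object@grids))))
  print(table(object@split))
})

#' Neural LAI regressor
#'
#' Parameter container for one model family: `"ann"` (feed-forward tanh
#' network on the flattened window), `"lstm"` (single-layer LSTM, last
#' hidden state to a linear head) or `"imv"` (interpretable multi-variable
#' LSTM with per-variable hidden blocks and a two-stage temporal/variable
#' attention mechanism).
#'
#' @export
setClass("LaiModel",
  representation(family = "character", params = "list", config = "list"),
  validity = function(object) {
    if (!object@family %in% c("ann", "lstm", "imv"))
      return("family must be ann, lstm or imv")
    TRUE
  }
)

#' @describeIn LaiModel-class model family string.
#' @param x a `LaiModel` object.
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))
#' @export
setMethod("modelFamily", "LaiModel", function(x) x@family)

#' @describeIn LaiModel-class nested list of parameter arrays.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @export
setMethod("modelParams", "LaiModel", function(x) x@params)

#' @describeIn LaiModel-class architecture configuration list.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @export
setMethod("modelConfig", "LaiModel", function(x) x@config)

setMethod("show", "LaiModel", function(object) {
  np <- length(treeUnlist(object@params))
  cat(sprintf("LaiModel <%s>: %d parameters\n", object@family, np))
})

#' Fitted model with training history
#'
#' Result of [fitModel()]: the parameters snapshotted at the epoch of
#' minimum validation loss, the per-epoch loss curves and the index of
#' that epoch.
#'
#' @export
setClass("LaiFit",
  representation(model = "LaiModel", history = "data.frame",
                 bestEpoch = "integer"),
  validity = function(object) {
    h <- object@history
    if (!all(c("epoch", "train_loss", "val_loss") %in% colnames(h)))
      return("history must carry epoch, train_loss, val_loss")
    if (nrow(h) > 0 && object@bestEpoch != which.min(h$val_loss))
      return("bestEpoch must be the argmin of the validation loss")
    TRUE
  }
)

#' @describeIn LaiFit-class the selected (min-validation-loss) model.
#' @param x a `LaiFit` object.
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @export
setMethod("bestModel", "LaiFit", function(x) x@model)

#' @describeIn LaiFit-class per-epoch train/validation loss curves.
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @export
setMethod("lossHistory", "LaiFit", function(x) x@history)

#' @describeIn LaiFit-class epoch index of the minimum validation loss.
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))
#' @export
setMethod("bestEpoch", "LaiFit", function(x) x@bestEpoch)

setMethod("show", "LaiFit", function(object) {
  cat(sprintf("LaiFit <%s>: %d epochs, best epoch %d (val loss %.4g)\n",
              object@model@family, nrow(object@history), object@bestEpoch,
              object@history$val_loss[object@bestEpoch]))
})
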