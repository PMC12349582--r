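#' Write gridded series to disk
#'
#' Writes three plain-text files to `dir`: `series.csv` (long format:
#' grid_id, date, soil_moisture, temperature, lai), `landcover.csv`
#' (grid_id, label, row, col) and `metadata.json` (units, calendar span,
#' generator settings).
#'
#' @param x a [LaiGrids-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeLaiGrids <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dates <- compositeDates(x)
  long <- data.frame(
    grid_id = rep(rownames(x), times = ncol(x)),
    date = rep(as.character(dates), each = nrow(x)),
    soil_moisture = as.vector(soilMoisture(x)),
    temperature = as.vector(airTemperature(x)),
    lai = as.vector(leafAreaIndex(x)))
  utils::write.csv(long, file.path(dir, "series.csv"), row.names = FALSE)
  rd <- as.data.frame(rowData(x))
  utils::write.csv(rd[c("grid_id", "landcover", "row", "col")],
                   file.path(dir, "landcover.csv"), row.names = FALSE)
  meta <- c(list(units = list(soil_moisture = "kg/m2",
                              temperature = "degC", lai = "m2/m2"),
                 calendar = "8-day composite, 46 per year",
                 n_grids = nrow(x), n_composites = ncol(x),
                 years = as.integer(unique(colData(x)$year))),
            S4Vectors::metadata(x))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read gridded series written by [writeLaiGrids()]
#'
#' @param dir directory holding `series.csv` and `landcover.csv`.
#' @return a [LaiGrids-class].
#' @export
readLaiGrids <- function(dir) {
  long <- utils::read.csv(file.path(dir, "series.csv"))
  lc <- utils::read.csv(file.path(dir, "landcover.csv"))
  gids <- lc$grid_id
  dates <- sort(unique(as.Date(long$date)))
  shape <- function(v) {
    m <- matrix(v[order(match(long$grid_id, gids),
                        as.Date(long$date))],
                nrow = length(gids), byrow = TRUE,
                dimnames = list(gids, NULL))
    m
  }
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  nd <- ifelse(doy == 361L, ifelse(leap, 6L, 5L), 8L)
  se <- SummarizedExperiment(
    assays = list(soil_moisture = shape(long$soil_moisture),
                  temperature = shape(long$temperature),
                  lai = shape(long$lai)),
    rowData = DataFrame(lc, row.names = gids),
    colData = DataFrame(index = seq_along(dates), year = yr, doy = doy,
                        date = dates, n_days = as.integer(nd)))
  new("LaiGrids", se)
}

## Serialize a parameter tree to JSON-safe structures (dims preserved).
.packParams <- function(p) {
  if (is.list(p)) return(lapply(p, .packParams))
  if (is.matrix(p)) return(list(.dim = dim(p), .data = as.vector(p)))
  p
}

.unpackParams <- function(p) {
  if (is.list(p)) {
    if (!is.null(p$.dim))
      return(matrix(unlist(p$.data), p$.dim[[1]], p$.dim[[2]]))
    return(lapply(p, .unpackParams))
  }
  p
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON files embedding the architecture configuration
#' (family, window, sizes, seed, normalization ranges) next to the
#' parameters, so predictions are reproducible from file alone.
#'
#' @param model a [LaiModel-class].
#' @param path checkpoint file path (`.json`).
#' @return `path` (write) / the restored [LaiModel-class] (read).
#' @export
writeModel <- function(model, path) {
  cfg <- modelConfig(model)
  cfg$ranges <- NULL
  jsonlite::write_json(
    list(family = modelFamily(model), config = cfg,
         params = .packParams(modelParams(model))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  restore <- function(p) {
    if (!is.list(p)) return(p)
    if (!is.null(p$.dim)) {
      d <- as.integer(unlist(p$.dim))
      return(matrix(as.numeric(unlist(p$.data)), d[1], d[2]))
    }
    scalarish <- vapply(p, function(e) is.numeric(e) && length(e) == 1L,
                        logical(1))
    if (is.null(names(p)) && length(p) && all(scalarish))
      return(as.numeric(unlist(p)))
    lapply(p, restore)
  }
  cfg <- restore(x$config)
  cfg$ranges <- variableRanges()
  new("LaiModel", family = x$family[[1]],
      params = restore(x$params), config = cfg)
}

#' Write / read windowed samples
#'
#' Samples are stored as a flat CSV (grid_id, target_date, split, target,
#' then the flattened window columns `sm_1..sm_w`, `t_1..t_w`) with a JSON
#' sidecar recording the window length, variable order and normalization
#' ranges.
#'
#' @param samples a [LaiSamples-class].
#' @param dir output directory (created if needed).
#' @return `dir` (write) / the restored [LaiSamples-class] (read).
#' @export
writeSamples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- samples@window
  X <- sampleInputs(samples)
  flat <- cbind(matrix(X[, , 1L], ncol = w), matrix(X[, , 2L], ncol = w))
  colnames(flat) <- c(paste0("sm_", seq_len(w)), paste0("t_", seq_len(w)))
  df <- data.frame(grid_id = sampleGrids(samples),
                   landcover = sampleLandcover(samples),
                   target_date = as.character(sampleDates(samples)),
                   split = as.character(sampleSplits(samples)),
                   target = sampleTargets(samples))
  utils::write.csv(cbind(df, flat), file.path(dir, "samples.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(window = w, variables = c("soil_moisture", "temperature"),
         ranges = variableRanges(), n_samples = length(samples)),
    file.path(dir, "samples.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSamples
#' @export
readSamples <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "samples.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "samples.csv"))
  w <- as.integer(meta$window)
  n <- nrow(df)
  inputs <- array(NA_real_, c(n, w, 2L),
                  dimnames = list(NULL, NULL,
                                  c("soil_moisture", "temperature")))
  inputs[, , 1L] <- as.matrix(df[paste0("sm_", seq_len(w))])
  inputs[, , 2L] <- as.matrix(df[paste0("t_", seq_len(w))])
  new("LaiSamples", inputs = inputs, targets = df$target,
      dates = as.Date(df$target_date), grids = df$grid_id,
      landcoverLabels = df$landcover,
      split = factor(df$split,
                     levels = c("train", "val", "test", "unassigned")),
      window = w, ranges = variableRanges())
}
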