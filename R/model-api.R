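#' Initialize a LAI regression model
#'
#' Weights are drawn uniformly in +/- 1/sqrt(fan-in) under the given seed;
#' biases start at zero. The default architectures follow the study
#' configuration (ANN hidden layers 32/256/256/32; recurrent hidden size
#' 256); [laiProfile()] provides a reduced test profile for minutes-scale
#' CPU runs.
#'
#' @param family `"ann"`, `"lstm"` or `"imv"`.
#' @param window input window length in composites (default 7).
#' @param n_vars number of input variables (default 2: soil moisture,
#'   temperature).
#' @param hidden hidden size of the recurrent families.
#' @param layers hidden-layer sizes of the ANN.
#' @param seed integer seed used for the initialization draw.
#' @return A [LaiModel-class].
#' @examples
#' m <- initModel("imv", hidden = 8, seed = 1)
#' imvForward(m, matrix(runif(14), 7, 2))$attention$variable
#' @export
initModel <- function(family = c("ann", "lstm", "imv"), window = 7L,
                      n_vars = 2L, hidden = 256L,
                      layers = c(32L, 256L, 256L, 32L), seed = 1L) {
  family <- match.arg(family)
  window <- assertCount(window, "window")
  n_vars <- assertCount(n_vars, "n_vars")
  hidden <- assertCount(hidden, "hidden")
  set.seed(seed)
  params <- switch(family,
    ann = annInit(window * n_vars, layers),
    lstm = lstmInit(n_vars, hidden),
    imv = imvInit(n_vars, hidden)
  )
  new("LaiModel", family = family, params = params,
      config = list(window = window, n_vars = n_vars, hidden = hidden,
                    layers = layers, seed = seed,
                    ranges = variableRanges()))
}

## Dispatch table used by training and prediction. Forward functions take
## (params, X[B, T, N], keep_cache) and return list(y, ..., cache);
## backward functions take (params, cache, dy).
.familyFns <- function(family) {
  switch(family,
    ann = list(
      fwd = function(p, X, keep_cache = FALSE) {
        annFwd(p, matrix(X, dim(X)[1]), keep_cache)
      },
      bwd = annBwd),
    lstm = list(fwd = lstmFwd, bwd = lstmBwd),
    imv = list(fwd = imvFwd, bwd = imvBwd),
    imvStop(paste("unknown model family:", family), "configurationError")
  )
}

#' Predict LAI for a set of samples
#'
#' @param model a [LaiModel-class].
#' @param samples a [LaiSamples-class].
#' @param split optional split tag(s) to predict on (default: all samples).
#' @param denormalize return predictions in m2/m2 instead of the
#'   normalized \[0, 1\] scale.
#' @return numeric vector of predictions, aligned with the (possibly
#'   subset) samples.
#' @export
predictLai <- function(model, samples, split = NULL, denormalize = FALSE) {
  if (!is.null(split)) samples <- subsetSamples(samples, split = split)
  fns <- .familyFns(modelFamily(model))
  y <- fns$fwd(modelParams(model), sampleInputs(samples))$y
  if (denormalize) y <- denormalizeValues(y, "lai")
  y
}

#' Attention records for a set of samples
#'
#' Runs the IMV-LSTM forward pass and returns the attention for every
#' sample: temporal weights per variable and the variable mixture weights
#' used as importance scores.
#'
#' @param model a [LaiModel-class] of family `"imv"`.
#' @param samples a [LaiSamples-class].
#' @param split optional split tag(s) to use.
#' @return list with `temporal` (`n x window x 2` array; for each sample
#'   and variable the weights over time sum to 1), `variable` (`n x 2`
#'   matrix of mixture weights, rows on the simplex) and `estimate`
#'   (normalized predictions).
#' @export
attentionRecords <- function(model, samples, split = NULL) {
  if (modelFamily(model) != "imv")
    imvStop("attention records require an imv model", "configurationError")
  if (!is.null(split)) samples <- subsetSamples(samples, split = split)
  out <- imvFwd(modelParams(model), sampleInputs(samples))
  list(temporal = out$alpha, variable = out$pr, estimate = out$y,
       samples = samples)
}
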