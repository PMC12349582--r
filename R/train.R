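#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001,
#' batch size 256, 300 epochs, mean-squared-error loss on normalized LAI,
#' no additional regularization; the parameters at the epoch of minimum
#' validation loss are retained (early-stopping-style model selection).
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size mini-batch size (>= 1); batches are reshuffled every
#'   epoch with the run seed, validation is evaluated full-batch.
#' @param epochs training epochs (>= 1).
#' @param seed integer seed controlling initialization order and shuffling.
#' @param finetune_epochs epochs used in the per-grid fine-tuning stage
#'   (defaults to `epochs`).
#' @return a validated configuration list.
#' @export
trainConfig <- function(learning_rate = 0.001, batch_size = 256L,
                        epochs = 300L, seed = 1L, finetune_epochs = epochs) {
  if (learning_rate <= 0)
    imvStop("learning_rate must be > 0", "invalidArgumentError")
  list(learning_rate = learning_rate,
       batch_size = assertCount(batch_size, "batch_size"),
       epochs = assertCount(epochs, "epochs"),
       seed = assertCount(seed, "seed", min = 0L),
       finetune_epochs = assertCount(finetune_epochs, "finetune_epochs"))
}

#' Named size profiles
#'
#' `"full"` is the full study configuration (hidden 256, ANN layers
#' 32/256/256/32, 300 epochs, batch 256); `"test"` is a reduced profile
#' (hidden 16, ANN layers 8/16/16/8, 100 epochs, batch 64) sized so the
#' whole pipeline trains in minutes on one CPU while preserving the
#' qualitative behaviour. The test profile's batch size scales with its
#' much smaller pooled sample sets, keeping the number of optimizer steps
#' per epoch meaningful.
#'
#' @param name `"full"` or `"test"`.
#' @return list with `hidden`, `layers`, `epochs`, `batch_size`,
#'   `learning_rate`.
#' @export
laiProfile <- function(name = c("test", "full")) {
  name <- match.arg(name)
  switch(name,
    full = list(hidden = 256L, layers = c(32L, 256L, 256L, 32L),
                 epochs = 300L, batch_size = 256L, learning_rate = 0.001),
    test = list(hidden = 16L, layers = c(8L, 16L, 16L, 8L),
                epochs = 100L, batch_size = 64L, learning_rate = 0.001)
  )
}

## One Adam update over a parameter tree. state holds m, v trees and the
## step counter.
adamStep <- function(theta, grad, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- treeMap2(state$m, grad, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- treeMap2(state$v, grad, function(v, g) b2 * v + (1 - b2) * g^2)
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  upd <- treeMap2(state$m, state$v,
                  function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  list(theta = treeMap2(theta, upd, `-`), state = state)
}

.mse <- function(y, t) mean((y - t)^2)

#' Fit a model with Adam and min-validation-loss selection
#'
#' Mini-batch Adam on the mean squared error of normalized LAI. After
#' every epoch the full-batch validation loss is recorded and the
#' parameters are snapshotted whenever a new minimum occurs; the returned
#' model carries the snapshot at the overall minimum.
#'
#' @param model a freshly initialized or pretrained [LaiModel-class]
#'   (its parameters are the starting point).
#' @param train_samples,val_samples [LaiSamples-class] objects (typically
#'   the `train` and `val` splits).
#' @param config a [trainConfig()] list.
#' @return a [LaiFit-class].
#' @export
fitModel <- function(model, train_samples, val_samples,
                     config = trainConfig()) {
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    imvStop("training and validation sets must be non-empty",
            "invalidArgumentError")
  fns <- .familyFns(modelFamily(model))
  theta <- modelParams(model)
  Xtr <- sampleInputs(train_samples); ytr <- sampleTargets(train_samples)
  Xva <- sampleInputs(val_samples); yva <- sampleTargets(val_samples)
  n <- length(ytr)

  set.seed(config$seed)
  state <- list(m = treeZero(theta), v = treeZero(theta), t = 0L)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(loss = Inf, theta = theta, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tl <- 0
    for (s in starts) {
      b <- idx[s:min(s + config$batch_size - 1L, n)]
      Xb <- Xtr[b, , , drop = FALSE]
      fw <- fns$fwd(theta, Xb, keep_cache = TRUE)
      err <- fw$y - ytr[b]
      tl <- tl + sum(err^2)
      dy <- 2 * err / length(b)
      grad <- fns$bwd(theta, fw$cache, dy)
      upd <- adamStep(theta, grad, state, config$learning_rate)
      theta <- upd$theta
      state <- upd$state
    }
    train_loss <- tl / n
    val_loss <- .mse(fns$fwd(theta, Xva)$y, yva)
    if (!is.finite(train_loss) || !is.finite(val_loss))
      imvStop(sprintf("non-finite loss at epoch %d", epoch),
              "trainingFailureError")
    hist$train_loss[epoch] <- train_loss
    hist$val_loss[epoch] <- val_loss
    if (val_loss < best$loss)
      best <- list(loss = val_loss, theta = theta, epoch = epoch)
  }
  new("LaiFit",
      model = new("LaiModel", family = modelFamily(model),
                  params = best$theta, config = modelConfig(model)),
      history = hist, bestEpoch = best$epoch)
}

#' Global pretraining followed by per-grid fine-tuning
#'
#' Fits one model on the pooled training samples of all grids, then uses
#' its selected parameters to initialize an independent fine-tuning fit on
#' each grid's own train/val samples (fresh optimizer state per grid),
#' producing a unique parameter set per grid.
#'
#' @param model the initialized [LaiModel-class] template.
#' @param samples a split-tagged [LaiSamples-class] covering all grids.
#' @param config a [trainConfig()]; fine-tuning runs `finetune_epochs`
#'   epochs with per-grid seeds derived from `seed`.
#' @param pretrain set `FALSE` to skip the pooled stage and fine-tune each
#'   grid from the template's fresh initialization.
#' @return list with `pretrain` (the pooled [LaiFit-class], or `NULL` when
#'   skipped) and `grids` (named list of per-grid fits).
#' @export
pretrainFinetune <- function(model, samples, config = trainConfig(),
                             pretrain = TRUE) {
  tr <- subsetSamples(samples, split = "train")
  va <- subsetSamples(samples, split = "val")
  if (length(tr) == 0L)
    imvStop("pooled training set is empty", "invalidArgumentError")
  pre <- NULL
  init <- model
  if (pretrain) {
    pre <- fitModel(model, tr, va, config)
    init <- bestModel(pre)
  }
  gids <- unique(sampleGrids(samples))
  fits <- vector("list", length(gids))
  names(fits) <- gids
  for (k in seq_along(gids)) {
    g <- gids[k]
    cfg <- config
    cfg$epochs <- config$finetune_epochs
    cfg$seed <- config$seed + k
    start <- if (pretrain) init else
      initModel(modelFamily(model),
                window = modelConfig(model)$window,
                n_vars = modelConfig(model)$n_vars,
                hidden = modelConfig(model)$hidden,
                layers = modelConfig(model)$layers,
                seed = cfg$seed)
    fits[[k]] <- fitModel(start,
                          subsetSamples(tr, grid = g),
                          subsetSamples(va, grid = g), cfg)
  }
  list(pretrain = pre, grids = fits)
}
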