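## Feed-forward (MLP) regressor on the flattened 7 x 2 input window:
## h(l) = tanh(W(l)' h(l-1) + b(l)) for each hidden layer, affine output.

.init_mat <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) / sqrt(nin), nin, nout)
}

annInit <- function(n_in, layers = c(32L, 256L, 256L, 32L)) {
  sizes <- c(n_in, layers, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- .init_mat(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

## X: B x n_in. Returns list(y = length-B predictions, cache).
annFwd <- function(params, X, keep_cache = FALSE) {
  L <- length(params$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    H[[l + 1L]] <- tanh(sweep(H[[l]] %*% params$W[[l]], 2L, params$b[[l]], "+"))
  }
  y <- drop(H[[L]] %*% params$W[[L]]) + params$b[[L]]
  list(y = y, cache = if (keep_cache) list(H = H) else NULL)
}

## dy: length-B gradient of the loss w.r.t. y. Returns grads shaped like params.
annBwd <- function(params, cache, dy) {
  L <- length(params$W)
  H <- cache$H
  gW <- vector("list", L); gb <- vector("list", L)
  gW[[L]] <- crossprod(H[[L]], dy)
  gb[[L]] <- sum(dy)
  dH <- dy %o% drop(params$W[[L]])
  for (l in rev(seq_len(L - 1L))) {
    dZ <- dH * (1 - H[[l + 1L]]^2)
    gW[[l]] <- crossprod(H[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dH <- dZ %*% t(params$W[[l]])
  }
  list(W = gW, b = gb)
}

#' Evaluate the feed-forward network on one flattened input
#'
#' Runs the tanh hidden-layer chain and the affine output head on a single
#' flattened window (length `window * 2`).
#'
#' @param model a `LaiModel` of family `"ann"` (see [initModel()]), or its
#'   parameter list.
#' @param x numeric input vector whose length matches the first layer.
#' @return scalar prediction on the normalized LAI scale.
#' @export
annForward <- function(model, x) {
  params <- if (is(model, "LaiModel")) modelParams(model) else model
  if (length(x) != nrow(params$W[[1]]))
    imvStop(sprintf("input length %d does not match first layer (%d)",
                    length(x), nrow(params$W[[1]])), "configurationError")
  annFwd(params, matrix(x, 1L))$y
}
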