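## Single-layer LSTM on the 7-step window; the last hidden state feeds an
## affine head. Gate equations:
##   i,f,o = sigmoid(W . [h_{t-1}, x_t] + b),  g = tanh(Wc . [h,x] + bc)
##   C_t = f * C_{t-1} + i * g,                h_t = o * tanh(C_t)
## Weights are stored transposed for right multiplication: (d + n_in) x d,
## rows 1..d acting on h_{t-1} and the rest on x_t.

lstmInit <- function(n_in, d) {
  list(
    Wi = .init_mat(d + n_in, d), Wf = .init_mat(d + n_in, d),
    Wo = .init_mat(d + n_in, d), Wc = .init_mat(d + n_in, d),
    bi = numeric(d), bf = numeric(d), bo = numeric(d), bc = numeric(d),
    w_out = .init_mat(d, 1L), b_out = 0
  )
}

## One batched step. H, C: B x d; Xt: B x n_in.
.lstm_step <- function(params, H, C, Xt) {
  A <- cbind(H, Xt)
  i <- sigmoid(sweep(A %*% params$Wi, 2L, params$bi, "+"))
  f <- sigmoid(sweep(A %*% params$Wf, 2L, params$bf, "+"))
  o <- sigmoid(sweep(A %*% params$Wo, 2L, params$bo, "+"))
  g <- tanh(sweep(A %*% params$Wc, 2L, params$bc, "+"))
  Cn <- f * C + i * g
  tC <- tanh(Cn)
  list(H = o * tC, C = Cn, A = A, i = i, f = f, o = o, g = g,
       Cprev = C, tC = tC)
}

## X: B x T x n_in. Returns predictions and (optionally) per-step caches.
lstmFwd <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  d <- ncol(params$Wi)
  H <- matrix(0, B, d); C <- matrix(0, B, d)
  steps <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    st <- .lstm_step(params, H, C, matrix(X[, t, ], nrow = B))
    H <- st$H; C <- st$C
    if (keep_cache) steps[[t]] <- st
  }
  y <- drop(H %*% params$w_out) + params$b_out
  list(y = y, cache = if (keep_cache) list(steps = steps, X = X) else NULL)
}

lstmBwd <- function(params, cache, dy) {
  steps <- cache$steps
  Tn <- length(steps)
  d <- ncol(params$Wi)
  g <- treeZero(params)
  HT <- steps[[Tn]]$H
  g$w_out <- crossprod(HT, dy)
  g$b_out <- sum(dy)
  dH <- dy %o% drop(params$w_out)
  dC <- matrix(0, nrow(dH), d)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    dC <- dC + dH * st$o * (1 - st$tC^2)
    dzo <- (dH * st$tC) * st$o * (1 - st$o)
    dzi <- (dC * st$g) * st$i * (1 - st$i)
    dzf <- (dC * st$Cprev) * st$f * (1 - st$f)
    dzg <- (dC * st$i) * (1 - st$g^2)
    g$Wi <- g$Wi + crossprod(st$A, dzi)
    g$Wf <- g$Wf + crossprod(st$A, dzf)
    g$Wo <- g$Wo + crossprod(st$A, dzo)
    g$Wc <- g$Wc + crossprod(st$A, dzg)
    g$bi <- g$bi + colSums(dzi); g$bf <- g$bf + colSums(dzf)
    g$bo <- g$bo + colSums(dzo); g$bc <- g$bc + colSums(dzg)
    dA <- dzi %*% t(params$Wi) + dzf %*% t(params$Wf) +
      dzo %*% t(params$Wo) + dzg %*% t(params$Wc)
    dH <- dA[, seq_len(d), drop = FALSE]
    dC <- dC * st$f
  }
  g
}

#' Single LSTM cell update
#'
#' Applies the gate equations once: update, forget and output gates are
#' sigmoids of affine maps of `[h, x]`; the candidate cell is a tanh of the
#' same; the cell state is `f * C + i * candidate` and the hidden state
#' `o * tanh(C_new)`.
#'
#' @param model a `LaiModel` of family `"lstm"` or its parameter list.
#' @param h,C previous hidden and cell state (length `d`).
#' @param x input vector at this step.
#' @return list with updated `h` and `C`.
#' @export
lstmStep <- function(model, h, C, x) {
  params <- if (is(model, "LaiModel")) modelParams(model) else model
  if (!all(is.finite(c(h, C, x))))
    imvStop("non-finite state or input", "numericalError")
  d <- ncol(params$Wi)
  if (length(h) != d || length(C) != d)
    imvStop("state dimension does not match the hidden size",
            "configurationError")
  st <- .lstm_step(params, matrix(h, 1L), matrix(C, 1L), matrix(x, 1L))
  list(h = drop(st$H), C = drop(st$C))
}

#' LSTM forward pass over an input window
#'
#' Iterates [lstmStep()] from the zero state over the sequence and applies
#' the affine output head to the final hidden state.
#'
#' @param model a `LaiModel` of family `"lstm"` or its parameter list.
#' @param X sequence as a `T x n_in` matrix (rows = time steps).
#' @return scalar prediction on the normalized LAI scale.
#' @export
lstmForward <- function(model, X) {
  params <- if (is(model, "LaiModel")) modelParams(model) else model
  X <- as.matrix(X)
  if (nrow(X) < 1L)
    imvStop("empty input sequence", "invalidArgumentError")
  X3 <- array(X, c(1L, nrow(X), ncol(X)))
  lstmFwd(params, X3)$y
}
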