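## Interpretable multi-variable LSTM (IMV-LSTM, tensorized cell).
##
## Each input variable n keeps its own hidden/cell block of size d; the
## candidate update and the three gates for variable n read only that
## variable's hidden state and scalar input (per-variable separation, the
## basis of the interpretability claim). The hidden-state sequence of each
## variable feeds a temporal attention (softmax over time of a learned
## per-variable scoring network), producing a context g_n; the variable
## attention is a softmax over variables of an affine score of
## h_T^n (+) g_n, giving mixture weights Pr(z = n). Per-variable affine
## heads mu_n on h_T^n (+) g_n are combined as y = sum_n Pr(z = n) mu_n.

imvInit <- function(n_vars, d) {
  one <- function() list(
    cell = list(Wi = .init_mat(d + 1L, d), Wf = .init_mat(d + 1L, d),
                Wo = .init_mat(d + 1L, d), Wc = .init_mat(d + 1L, d),
                bi = numeric(d), bf = numeric(d), bo = numeric(d),
                bc = numeric(d)),
    attn = list(V1 = .init_mat(d, d), c1 = numeric(d),
                v2 = .init_mat(d, 1L), c2 = 0),
    head = list(w_s = .init_mat(2L * d, 1L), b_s = 0,
                w_m = .init_mat(2L * d, 1L), b_m = 0)
  )
  list(vars = lapply(seq_len(n_vars), function(n) one()))
}

## X: B x T x N (one scalar input per variable per step).
imvFwd <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; N <- dim(X)[3]
  d <- ncol(params$vars[[1]]$cell$Wi)
  Hseq <- vector("list", N)
  steps <- vector("list", N)
  Pmats <- vector("list", N)
  alpha <- array(NA_real_, c(B, Tn, N))
  G <- vector("list", N)
  U <- vector("list", N)
  S <- matrix(NA_real_, B, N)
  M <- matrix(NA_real_, B, N)
  for (n in seq_len(N)) {
    pv <- params$vars[[n]]
    H <- matrix(0, B, d); C <- matrix(0, B, d)
    Hs <- vector("list", Tn)
    sts <- if (keep_cache) vector("list", Tn) else NULL
    for (t in seq_len(Tn)) {
      st <- .lstm_step(pv$cell, H, C, matrix(X[, t, n], nrow = B))
      H <- st$H; C <- st$C
      Hs[[t]] <- H
      if (keep_cache) sts[[t]] <- st
    }
    ## temporal attention: scores via tanh layer, softmax over time
    E <- matrix(NA_real_, B, Tn)
    Ps <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      P <- tanh(sweep(Hs[[t]] %*% pv$attn$V1, 2L, pv$attn$c1, "+"))
      Ps[[t]] <- P
      E[, t] <- drop(P %*% pv$attn$v2) + pv$attn$c2
    }
    a <- rowSoftmax(E)
    gctx <- matrix(0, B, d)
    for (t in seq_len(Tn)) gctx <- gctx + a[, t] * Hs[[t]]
    u <- cbind(Hs[[Tn]], gctx)
    alpha[, , n] <- a
    G[[n]] <- gctx
    U[[n]] <- u
    S[, n] <- drop(u %*% pv$head$w_s) + pv$head$b_s
    M[, n] <- drop(u %*% pv$head$w_m) + pv$head$b_m
    Hseq[[n]] <- Hs
    steps[[n]] <- sts
    Pmats[[n]] <- Ps
  }
  Pr <- rowSoftmax(S)
  y <- rowSums(Pr * M)
  cache <- if (keep_cache) {
    list(X = X, Hseq = Hseq, steps = steps, Pmats = Pmats, alpha = alpha,
         U = U, Pr = Pr, M = M, d = d)
  }
  list(y = y, alpha = alpha, pr = Pr, mu = M, g = G, cache = cache)
}

imvBwd <- function(params, cache, dy) {
  N <- length(params$vars)
  Tn <- dim(cache$alpha)[2]
  d <- cache$d
  Pr <- cache$Pr; M <- cache$M
  g <- treeZero(params)

  dM <- Pr * dy
  dPrRaw <- M * dy
  dS <- Pr * (dPrRaw - rowSums(dPrRaw * Pr))

  for (n in seq_len(N)) {
    pv <- params$vars[[n]]
    u <- cache$U[[n]]
    Hs <- cache$Hseq[[n]]
    a <- cache$alpha[, , n, drop = FALSE][, , 1L]
    if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
    gn <- g$vars[[n]]

    gn$head$w_m <- crossprod(u, dM[, n])
    gn$head$b_m <- sum(dM[, n])
    gn$head$w_s <- crossprod(u, dS[, n])
    gn$head$b_s <- sum(dS[, n])
    du <- dM[, n] %o% drop(pv$head$w_m) + dS[, n] %o% drop(pv$head$w_s)
    dHT <- du[, seq_len(d), drop = FALSE]
    dg <- du[, d + seq_len(d), drop = FALSE]

    ## attention backward
    dalpha <- matrix(NA_real_, nrow(dg), Tn)
    for (t in seq_len(Tn)) dalpha[, t] <- rowSums(dg * Hs[[t]])
    dE <- a * (dalpha - rowSums(dalpha * a))
    dH_att <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      P <- cache$Pmats[[n]][[t]]
      dP <- dE[, t] %o% drop(pv$attn$v2)
      dZ <- dP * (1 - P^2)
      gn$attn$V1 <- gn$attn$V1 + crossprod(Hs[[t]], dZ)
      gn$attn$c1 <- gn$attn$c1 + colSums(dZ)
      gn$attn$v2 <- gn$attn$v2 + crossprod(P, dE[, t])
      gn$attn$c2 <- gn$attn$c2 + sum(dE[, t])
      dH_att[[t]] <- a[, t] * dg + dZ %*% t(pv$attn$V1)
    }

    ## BPTT through this variable's cell, injecting the attention gradient
    dH <- dHT + dH_att[[Tn]]
    dC <- matrix(0, nrow(dH), d)
    for (t in rev(seq_len(Tn))) {
      st <- cache$steps[[n]][[t]]
      dC <- dC + dH * st$o * (1 - st$tC^2)
      dzo <- (dH * st$tC) * st$o * (1 - st$o)
      dzi <- (dC * st$g) * st$i * (1 - st$i)
      dzf <- (dC * st$Cprev) * st$f * (1 - st$f)
      dzg <- (dC * st$i) * (1 - st$g^2)
      gn$cell$Wi <- gn$cell$Wi + crossprod(st$A, dzi)
      gn$cell$Wf <- gn$cell$Wf + crossprod(st$A, dzf)
      gn$cell$Wo <- gn$cell$Wo + crossprod(st$A, dzo)
      gn$cell$Wc <- gn$cell$Wc + crossprod(st$A, dzg)
      gn$cell$bi <- gn$cell$bi + colSums(dzi)
      gn$cell$bf <- gn$cell$bf + colSums(dzf)
      gn$cell$bo <- gn$cell$bo + colSums(dzo)
      gn$cell$bc <- gn$cell$bc + colSums(dzg)
      dA <- dzi %*% t(pv$cell$Wi) + dzf %*% t(pv$cell$Wf) +
        dzo %*% t(pv$cell$Wo) + dzg %*% t(pv$cell$Wc)
      dH <- dA[, seq_len(d), drop = FALSE]
      if (t > 1L) dH <- dH + dH_att[[t - 1L]]
      dC <- dC * st$f
    }
    g$vars[[n]] <- gn
  }
  g
}

#' One tensorized IMV-LSTM cell update
#'
#' Updates every variable's hidden/cell block independently: variable `n`'s
#' gates and candidate read only its own hidden state `h[n, ]` and scalar
#' input `x[n]`.
#'
#' @param model a `LaiModel` of family `"imv"` or its parameter list.
#' @param h,C previous per-variable states, `N x d` matrices.
#' @param x length-`N` input (one scalar per variable).
#' @return list with updated `h` and `C` (`N x d`).
#' @export
imvStep <- function(model, h, C, x) {
  params <- if (is(model, "LaiModel")) modelParams(model) else model
  N <- length(params$vars)
  if (nrow(h) != N || length(x) != N)
    imvStop(sprintf("expected %d variables", N), "configurationError")
  for (n in seq_len(N)) {
    st <- .lstm_step(params$vars[[n]]$cell, matrix(h[n, ], 1L),
                     matrix(C[n, ], 1L), matrix(x[n], 1L))
    h[n, ] <- st$H
    C[n, ] <- st$C
  }
  list(h = h, C = C)
}

#' Temporal attention over one variable's hidden-state sequence
#'
#' Scores each hidden state with the variable's scoring network
#' `f(h) = v2' tanh(V1' h + c1) + c2`, softmaxes the scores over time and
#' returns the weights together with the attention-weighted sum of the
#' hidden states.
#'
#' @param H `T x d` matrix of hidden states (rows = time steps).
#' @param f scoring parameters: list with `V1` (d x d), `c1` (d),
#'   `v2` (d x 1) and `c2` (scalar).
#' @return list with `alpha` (length `T`, non-negative, sums to 1) and
#'   `g` (length `d` context vector).
#' @export
temporalAttention <- function(H, f) {
  H <- as.matrix(H)
  if (nrow(H) < 1L)
    imvStop("empty hidden-state sequence", "invalidArgumentError")
  P <- tanh(sweep(H %*% f$V1, 2L, f$c1, "+"))
  e <- drop(P %*% f$v2) + f$c2
  alpha <- softmax(e)
  list(alpha = alpha, g = drop(crossprod(H, alpha)))
}

#' IMV-LSTM forward pass with attention record
#'
#' Runs the tensorized cell over the window, applies temporal attention per
#' variable and the variable attention across variables, and returns the
#' mixture prediction together with the attention record.
#'
#' @param model a `LaiModel` of family `"imv"` or its parameter list.
#' @param X window as a `T x N` matrix (rows = time steps, columns =
#'   variables; here N = 2: soil moisture, temperature).
#' @return list with `estimate` (scalar, normalized LAI scale) and
#'   `attention`: `temporal` (`T x N`, each column sums to 1), `variable`
#'   (length-`N` simplex of mixture weights Pr(z = n)) and `context`
#'   (per-variable context vectors g_n).
#' @export
imvForward <- function(model, X) {
  params <- if (is(model, "LaiModel")) modelParams(model) else model
  X <- as.matrix(X)
  if (nrow(X) < 1L)
    imvStop("empty input sequence", "invalidArgumentError")
  if (ncol(X) != length(params$vars))
    imvStop("number of input variables does not match the model",
            "configurationError")
  X3 <- array(X, c(1L, nrow(X), ncol(X)))
  out <- imvFwd(params, X3)
  list(estimate = out$y,
       attention = list(temporal = matrix(out$alpha[1L, , ], nrow(X)),
                        variable = drop(out$pr),
                        context = lapply(out$g, function(m) drop(m[1L, ]))))
}

## Attention-record invariant check used by downstream extraction.
checkAttentionRecord <- function(temporal, variable, tol = 1e-6) {
  ok <- all(temporal >= -tol) && all(variable >= -tol) &&
    all(abs(colSums(temporal) - 1) <= tol) &&
    abs(sum(variable) - 1) <= tol
  if (!ok)
    imvStop("attention record violates its simplex invariants",
            "integrityError")
  invisible(TRUE)
}
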