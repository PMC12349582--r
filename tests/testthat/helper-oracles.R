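# Independent oracles: scalar-loop evaluations of the cell equations and a
# central-difference gradient, kept deliberately naive so they share no code
# with the batched implementations they check.

num_grad <- function(fwd, theta, eps = 1e-6) {
  flat <- unlist(theta)
  g <- numeric(length(flat))
  for (k in seq_along(flat)) {
    up <- flat; up[k] <- up[k] + eps
    dn <- flat; dn[k] <- dn[k] - eps
    g[k] <- (fwd(utils::relist(up, theta)) - fwd(utils::relist(dn, theta))) /
      (2 * eps)
  }
  g
}

sig <- function(z) 1 / (1 + exp(-z))

# Literal element-wise evaluation of the LSTM gate equations.
scalar_lstm_step <- function(p, h, C, x) {
  d <- length(h)
  a <- c(h, x)
  hn <- numeric(d); Cn <- numeric(d)
  for (k in seq_len(d)) {
    i <- sig(sum(p$Wi[, k] * a) + p$bi[k])
    f <- sig(sum(p$Wf[, k] * a) + p$bf[k])
    o <- sig(sum(p$Wo[, k] * a) + p$bo[k])
    g <- tanh(sum(p$Wc[, k] * a) + p$bc[k])
    Cn[k] <- f * C[k] + i * g
    hn[k] <- o * tanh(Cn[k])
  }
  list(h = hn, C = Cn)
}

# Per-variable scalar-loop evaluation of the tensorized cell.
scalar_imv_step <- function(params, h, C, x) {
  N <- length(params$vars)
  for (n in seq_len(N)) {
    st <- scalar_lstm_step(params$vars[[n]]$cell, h[n, ], C[n, ], x[n])
    h[n, ] <- st$h
    C[n, ] <- st$C
  }
  list(h = h, C = C)
}

# Direct softmax-over-time attention (no stabilisation tricks).
scalar_attention <- function(H, f) {
  e <- apply(H, 1L, function(h) {
    sum(f$v2 * tanh(colSums(f$V1 * h) + f$c1)) + f$c2
  })
  a <- exp(e) / sum(exp(e))
  list(alpha = a, g = colSums(a * H))
}

# Full IMV forward composed from the scalar pieces above.
scalar_imv_forward <- function(params, X) {
  N <- ncol(X); Tn <- nrow(X)
  d <- ncol(params$vars[[1]]$cell$Wi)
  h <- matrix(0, N, d); C <- matrix(0, N, d)
  Hs <- lapply(seq_len(N), function(n) matrix(NA_real_, Tn, d))
  for (t in seq_len(Tn)) {
    st <- scalar_imv_step(params, h, C, X[t, ])
    h <- st$h; C <- st$C
    for (n in seq_len(N)) Hs[[n]][t, ] <- h[n, ]
  }
  s <- numeric(N); mu <- numeric(N)
  alpha <- matrix(NA_real_, Tn, N)
  for (n in seq_len(N)) {
    at <- scalar_attention(Hs[[n]], params$vars[[n]]$attn)
    alpha[, n] <- at$alpha
    u <- c(h[n, ], at$g)
    s[n] <- sum(params$vars[[n]]$head$w_s * u) + params$vars[[n]]$head$b_s
    mu[n] <- sum(params$vars[[n]]$head$w_m * u) + params$vars[[n]]$head$b_m
  }
  pr <- exp(s) / sum(exp(s))
  list(y = sum(pr * mu), pr = pr, alpha = alpha)
}

# Tiny random parameter sets (internal initializers, fixed by set.seed at
# the call site).
tiny_lstm <- function(d = 3L, n_in = 2L) imvLAI:::lstmInit(n_in, d)
tiny_imv <- function(d = 2L, N = 2L) imvLAI:::imvInit(N, d)

# Build a LaiGrids container directly from matrices (bypasses the
# generator) for preprocess tests.
make_grids <- function(sm, ta, la, start_year = 2001L,
                       landcover = rep("grassland", nrow(sm))) {
  ng <- nrow(sm)
  years <- ceiling(ncol(sm) / 46L)
  cal <- compositeCalendar(start_year, years)[seq_len(ncol(sm)), ]
  gids <- sprintf("g%03d", seq_len(ng))
  rownames(sm) <- rownames(ta) <- rownames(la) <- gids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(soil_moisture = sm, temperature = ta, lai = la),
    rowData = S4Vectors::DataFrame(grid_id = gids, row = seq_len(ng),
                                   col = 1L, landcover = landcover,
                                   row.names = gids),
    colData = S4Vectors::DataFrame(cal))
  new("LaiGrids", se)
}

# Small simulated dataset shared by training/interpretation tests.
tiny_dataset <- function(lambda = 0.5, years = 4, seed = 1L,
                         labels = c("forest", "grassland")) {
  spec <- gridSpec(1L, length(labels), landcover = labels)
  x <- simulateLaiGrids(spec, years,
                        couplingParams(dominance_lambda = lambda),
                        seed = seed)
  splitChronological(buildSamples(x))
}
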