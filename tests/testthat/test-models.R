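test_that("ANN forward matches hand evaluation of the tanh chain", {
  ## all-zero parameters -> tanh(0) chain -> 0
  set.seed(1)
  p0 <- imvLAI:::treeZero(imvLAI:::annInit(14, c(4, 4)))
  expect_equal(annForward(p0, rep(0.3, 14)), 0)
  ## one-unit-per-layer toy: y = w3 tanh(w2 tanh(w1 x + b1) + b2) + b3
  p <- list(W = list(matrix(0.5, 1, 1), matrix(-1.2, 1, 1),
                     matrix(2, 1, 1)),
            b = list(0.1, -0.3, 0.05))
  x <- 0.7
  hand <- 2 * tanh(-1.2 * tanh(0.5 * x + 0.1) - 0.3) + 0.05
  expect_equal(annForward(p, x), hand, tolerance = 1e-12)
  expect_error(annForward(p, c(1, 2)), class = "configurationError")
})

test_that("ANN with single-unit layers is affine in the small-signal limit", {
  p <- list(W = list(matrix(0.4, 1, 1), matrix(-0.8, 1, 1),
                     matrix(1.5, 1, 1)),
            b = list(0, 0, 0))
  slope <- 1.5 * (-0.8) * 0.4  # product of weights = gain of linearization
  eps <- 1e-5
  expect_equal(annForward(p, eps) / eps, slope, tolerance = 1e-6)
})

test_that("ANN predictions are invariant to batch order", {
  set.seed(3)
  p <- imvLAI:::annInit(6, c(5, 4))
  X <- matrix(rnorm(30), 5, 6)
  y <- imvLAI:::annFwd(p, X)$y
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(imvLAI:::annFwd(p, X[perm, ])$y, y[perm], tolerance = 1e-12)
})

test_that("LSTM cell matches a scalar-loop oracle and its limiting cases", {
  ## zero parameters, zero state: i = f = o = 0.5, g = 0 -> h = C = 0
  set.seed(2)
  p0 <- imvLAI:::treeZero(tiny_lstm(3, 2))
  st <- lstmStep(p0, numeric(3), numeric(3), c(0.4, -0.2))
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$C, rep(0, 3))
  ## random tiny instances vs the element-wise oracle
  set.seed(11)
  for (rep in 1:30) {
    p <- tiny_lstm(3, 2)
    h <- rnorm(3); C <- rnorm(3); x <- rnorm(2)
    got <- lstmStep(p, h, C, x)
    want <- scalar_lstm_step(p, h, C, x)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$C, want$C, tolerance = 1e-10)
  }
  ## saturated gates: f ~ 1 and i ~ 0 pass the cell state through
  psat <- imvLAI:::treeZero(tiny_lstm(3, 2))
  psat$bf <- rep(30, 3); psat$bi <- rep(-30, 3)
  C <- c(0.7, -1.1, 0.2)
  st2 <- lstmStep(psat, numeric(3), C, c(1, 1))
  expect_equal(st2$C, C, tolerance = 1e-6)
  expect_error(lstmStep(psat, c(NA, 1, 2), C, c(1, 1)),
               class = "numericalError")
  expect_error(lstmStep(psat, numeric(2), numeric(2), c(1, 1)),
               class = "configurationError")
})

test_that("LSTM forward equals the step-by-step composition", {
  set.seed(4)
  p <- tiny_lstm(3, 2)
  X <- matrix(rnorm(14), 7, 2)
  ## iterate the exported step and apply the head by hand
  h <- numeric(3); C <- numeric(3)
  for (t in 1:7) {
    st <- lstmStep(p, h, C, X[t, ])
    h <- st$h; C <- st$C
  }
  want <- sum(h * drop(p$w_out)) + p$b_out
  expect_equal(lstmForward(p, X), want, tolerance = 1e-10)
  ## zero parameters -> zero estimate; length-1 sequence reduces to one step
  p0 <- imvLAI:::treeZero(p)
  expect_equal(lstmForward(p0, X), 0)
  st1 <- lstmStep(p, numeric(3), numeric(3), X[1, ])
  expect_equal(lstmForward(p, X[1, , drop = FALSE]),
               sum(st1$h * drop(p$w_out)) + p$b_out, tolerance = 1e-12)
  expect_error(lstmForward(p, X[0, , drop = FALSE]),
               class = "invalidArgumentError")
})

test_that("IMV cell keeps per-variable blocks separate and matches its oracle", {
  set.seed(5)
  p <- tiny_imv(2, 2)
  h <- matrix(rnorm(4), 2, 2); C <- matrix(rnorm(4), 2, 2)
  x <- c(0.3, -0.6)
  ## oracle agreement
  got <- imvStep(p, h, C, x)
  want <- scalar_imv_step(p, h, C, x)
  expect_equal(got$h, want$h, tolerance = 1e-10)
  ## zero parameters, zero state -> zero hidden state
  p0 <- imvLAI:::treeZero(p)
  st0 <- imvStep(p0, matrix(0, 2, 2), matrix(0, 2, 2), c(0, 0))
  expect_equal(st0$h, matrix(0, 2, 2))
  ## perturbing variable 1's input leaves variable 2's block unchanged
  got2 <- imvStep(p, h, C, c(9, -0.6))
  expect_equal(got2$h[2, ], got$h[2, ])
  expect_false(isTRUE(all.equal(got2$h[1, ], got$h[1, ])))
  ## and variable 2's parameters do not affect variable 1's block
  p2 <- p
  p2$vars[[2]]$cell$Wi <- p2$vars[[2]]$cell$Wi + 1
  expect_equal(imvStep(p2, h, C, x)$h[1, ], got$h[1, ])
  expect_error(imvStep(p, h[1, , drop = FALSE], C, x),
               class = "configurationError")
})

test_that("temporal attention is a softmax over learned scores", {
  set.seed(6)
  d <- 3
  f <- list(V1 = matrix(rnorm(9), 3, 3), c1 = rnorm(3),
            v2 = matrix(rnorm(3), 3, 1), c2 = 0.2)
  H <- matrix(rnorm(21), 7, 3)
  got <- temporalAttention(H, f)
  want <- scalar_attention(H, f)
  expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
  expect_equal(got$g, want$g, tolerance = 1e-12)
  ## constant scoring function -> uniform weights
  f0 <- list(V1 = matrix(0, 3, 3), c1 = rep(0, 3),
             v2 = matrix(0, 3, 1), c2 = 5)
  expect_equal(temporalAttention(H, f0)$alpha, rep(1 / 7, 7))
  ## single step -> weight 1 and g = h1
  got1 <- temporalAttention(H[1, , drop = FALSE], f)
  expect_equal(got1$alpha, 1)
  expect_equal(got1$g, H[1, ])
  expect_error(temporalAttention(H[0, , drop = FALSE], f),
               class = "invalidArgumentError")
})

test_that("IMV forward equals the composition of its scalar oracles", {
  set.seed(7)
  for (rep in 1:5) {
    p <- tiny_imv(2, 2)
    X <- matrix(rnorm(14), 7, 2)
    got <- imvForward(p, X)
    want <- scalar_imv_forward(p, X)
    expect_equal(got$estimate, want$y, tolerance = 1e-8)
    expect_equal(got$attention$variable, want$pr, tolerance = 1e-8)
    expect_equal(got$attention$temporal, want$alpha, tolerance = 1e-8)
  }
})

test_that("symmetric variables receive equal mixture weights", {
  set.seed(8)
  p <- tiny_imv(3, 2)
  p$vars[[2]] <- p$vars[[1]]  # identical parameter blocks
  X <- matrix(rep(rnorm(7), 2), 7, 2)  # identical inputs
  out <- imvForward(p, X)
  expect_equal(out$attention$variable, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("attention records satisfy their simplex invariants on random inputs", {
  set.seed(9)
  for (rep in 1:20) {
    p <- tiny_imv(2, 2)
    X <- matrix(rnorm(14, sd = 2), 7, 2)
    out <- imvForward(p, X)
    a <- out$attention$temporal
    v <- out$attention$variable
    expect_true(all(a >= 0) && all(v >= 0))
    expect_equal(colSums(a), c(1, 1), tolerance = 1e-6)
    expect_equal(sum(v), 1, tolerance = 1e-6)
  }
})

test_that("analytic gradients match central differences for all families", {
  set.seed(10)
  B <- 3
  ## ANN
  p <- imvLAI:::annInit(6, c(4, 3))
  X <- matrix(rnorm(B * 6), B, 6); tgt <- rnorm(B)
  fw <- imvLAI:::annFwd(p, X, TRUE)
  an <- unlist(imvLAI:::annBwd(p, fw$cache, 2 * (fw$y - tgt) / B))
  nu <- num_grad(function(pp) mean((imvLAI:::annFwd(pp, X)$y - tgt)^2), p)
  expect_lt(max(abs(an - nu)), 1e-6)
  ## LSTM
  p <- tiny_lstm(4, 2)
  X3 <- array(rnorm(B * 5 * 2), c(B, 5, 2)); tgt <- rnorm(B)
  fw <- imvLAI:::lstmFwd(p, X3, TRUE)
  an <- unlist(imvLAI:::lstmBwd(p, fw$cache, 2 * (fw$y - tgt) / B))
  nu <- num_grad(function(pp) mean((imvLAI:::lstmFwd(pp, X3)$y - tgt)^2), p)
  expect_lt(max(abs(an - nu)), 1e-6)
  ## IMV (cell + attention + mixture all at once)
  p <- tiny_imv(3, 2)
  X3 <- array(rnorm(B * 5 * 2), c(B, 5, 2)); tgt <- rnorm(B)
  fw <- imvLAI:::imvFwd(p, X3, TRUE)
  an <- unlist(imvLAI:::imvBwd(p, fw$cache, 2 * (fw$y - tgt) / B))
  nu <- num_grad(function(pp) mean((imvLAI:::imvFwd(pp, X3)$y - tgt)^2), p)
  expect_lt(max(abs(an - nu)), 1e-6)
})

test_that("model checkpoints roundtrip through JSON with identical predictions", {
  m <- initModel("imv", hidden = 4, seed = 3)
  path <- tempfile(fileext = ".json")
  writeModel(m, path)
  m2 <- readModel(path)
  X <- matrix(runif(14), 7, 2)
  expect_identical(modelFamily(m2), "imv")
  expect_equal(imvForward(m2, X)$estimate, imvForward(m, X)$estimate,
               tolerance = 1e-12)
  ## lstm family too
  ml <- initModel("lstm", hidden = 5, seed = 4)
  writeModel(ml, path)
  expect_equal(lstmForward(readModel(path), X), lstmForward(ml, X),
               tolerance = 1e-12)
})
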