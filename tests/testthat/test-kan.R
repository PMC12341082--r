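# KAN structure: edge activations, layer/network forward, initialization,
# backprop correctness, and the training loop.

test_that("silu has the right values and tails", {
  expect_equal(silu(0), 0)
  expect_equal(silu(30), 30, tolerance = 1e-8)       # sigmoid -> 1
  v <- silu(-20)
  expect_true(v > -1e-7 && v < 0)
  expect_equal(silu(1.3), 1.3 / (1 + exp(-1.3)))
  expect_true(all(is.finite(silu(c(-1e6, 1e6)))))
})

test_that("edge_activation combines SiLU and spline, with optional ReLU", {
  g <- uniform_grid(5, 3, -1, 1)
  p <- edge_params(1, 0, rep(0, n_bases(g)), g)
  expect_equal(edge_activation(0, p), 0)
  expect_equal(edge_activation(0, p, use_relu = TRUE), 0)
  # a negative pre-activation is clipped by the ReLU variant
  pneg <- edge_params(1, 0, rep(0, n_bases(g)), g)
  expect_lt(edge_activation(-3.2, pneg), 0)
  expect_equal(edge_activation(-3.2, pneg, use_relu = TRUE), 0)
})

test_that("edge activations are invariant to the (w_s, c) scaling ray", {
  set.seed(5)
  xs <- runif(50L, -2, 2)
  for (use_relu in c(FALSE, TRUE)) {
    p <- random_edge()
    base <- edge_activation(xs, p, use_relu)
    for (cc in c(0.1, 3, 250)) {
      p2 <- edge_params(p$w_b, p$w_s * cc, p$coeffs / cc, p$grid)
      expect_equal(edge_activation(xs, p2, use_relu), base, tolerance = 1e-9)
    }
  }
})

test_that("layer_forward sums per-edge activations at each node", {
  set.seed(15)
  m <- random_model(c(3, 4, 2), task = "coordinates")
  layer <- m$layers[[1]]
  # null parameters give the zero vector
  null_layer <- layer
  null_layer$Wb[] <- 0; null_layer$Ws[] <- 0
  expect_equal(layer_forward(c(0.3, -1, 2), null_layer), rep(0, 4))
  # naive double-loop oracle over edge_params objects
  for (relu in c(TRUE, FALSE)) {
    X <- matrix(runif(15L, -1.5, 1.5), 5L, 3L)
    got <- layer_forward(X, layer, apply_relu = relu)
    want <- matrix(0, 5L, 4L)
    for (o in 1:4) for (i in 1:3) {
      want[, o] <- want[, o] +
        edge_activation(X[, i], winnowkan:::layer_edge(layer, o, i), relu)
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(layer_forward(c(1, 2), layer), "expects")
})

test_that("an in_dim-1 layer output is the single edge activation", {
  set.seed(25)
  m <- random_model(c(1, 3, 2), task = "coordinates")
  layer <- m$layers[[1]]
  x <- runif(7L, -1, 1)
  got <- layer_forward(matrix(x, ncol = 1L), layer)
  for (o in 1:3) {
    expect_equal(got[, o],
                 edge_activation(x, winnowkan:::layer_edge(layer, o, 1L),
                                 layer$use_relu),
                 tolerance = 1e-10)
  }
})

test_that("kan_forward composes layers row-wise", {
  set.seed(35)
  m <- random_model(c(3, 2, 1), task = "ordinal", n_classes = 4)
  X <- matrix(runif(12L, 0, 2), 4L, 3L)
  # manual chaining of layer_forward (final layer exempt from ReLU)
  h <- layer_forward(X, m$layers[[1]], apply_relu = TRUE)
  h <- layer_forward(h, m$layers[[2]], apply_relu = FALSE)
  want <- winnowkan:::ordinal_head(h[, 1], m$head_bias)
  expect_equal(kan_forward(X, m), want, tolerance = 1e-12)
  # identical rows give identical outputs
  Xr <- X[rep(2L, 3L), ]
  out <- kan_forward(Xr, m)
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[2, ], out[3, ])
  # wrong gene count names the expectation
  expect_error(kan_forward(X[, 1:2], m), "expects 3 genes")
  # null parameters propagate zeros (head biases still added)
  mz <- m
  for (l in 1:2) { mz$layers[[l]]$Wb[] <- 0; mz$layers[[l]]$Ws[] <- 0 }
  expect_equal(unname(kan_forward(X, mz)[1, ]),
               sort(mz$head_bias, decreasing = TRUE))
})

test_that("init_model is seed-deterministic and validates dims", {
  m1 <- init_model(c(10, 1, 5, 2), task = "coordinates", seed = 42)
  m2 <- init_model(c(10, 1, 5, 2), task = "coordinates", seed = 42)
  expect_identical(m1, m2)
  m3 <- init_model(c(10, 1, 5, 2), task = "coordinates", seed = 43)
  expect_false(identical(m1$layers[[1]]$C, m3$layers[[1]]$C))
  expect_error(init_model(c(4, 2, 1), task = "coordinates"), "output dim")
  expect_error(init_model(c(4, 0, 2), task = "coordinates"), "positive")
  expect_error(init_model(c(4, 1), task = "ordinal", n_classes = 1), "n_classes")
  expect_error(init_model(c(4, 3), task = "categorical", n_classes = 4),
               "output dim")
})

test_that("whole-network output is invariant to per-edge (w_s, c) rescaling", {
  set.seed(45)
  for (relu in c(TRUE, FALSE)) {
    m <- random_model(c(5, 3, 2), task = "coordinates", use_relu = relu)
    X <- matrix(runif(40L, 0, 2), 8L, 5L)
    base <- kan_forward(X, m)
    m2 <- m
    for (l in seq_along(m2$layers)) {
      la <- m2$layers[[l]]
      cc <- matrix(runif(length(la$Ws), 0.2, 5), nrow(la$Ws))
      m2$layers[[l]]$Ws <- la$Ws * cc
      m2$layers[[l]]$C <- la$C / array(cc, dim(la$C))
    }
    expect_equal(kan_forward(X, m2), base, tolerance = 1e-8)
  }
})

test_that("ReLU and plain variants agree when pre-activations are non-negative", {
  set.seed(55)
  # positive weights, non-negative coefficients and inputs keep every edge
  # pre-activation >= 0
  mk <- function(relu) {
    m <- init_model(c(4, 3, 2), task = "coordinates", use_relu = relu, seed = 9)
    for (l in seq_along(m$layers)) {
      m$layers[[l]]$C <- abs(m$layers[[l]]$C)
      m$layers[[l]]$Ws <- abs(m$layers[[l]]$Ws)
    }
    m
  }
  X <- matrix(runif(20L, 0, 2), 5L, 4L)
  expect_equal(kan_forward(X, mk(TRUE)), kan_forward(X, mk(FALSE)),
               tolerance = 1e-12)
})

test_that("backprop matches central finite differences", {
  set.seed(65)
  m <- init_model(c(4, 3, 1), task = "ordinal", n_classes = 4,
                  G = 3, kappa = 2, seed = 7)
  n <- 10L
  X <- matrix(runif(n * 4L, -0.8, 0.8), n, 4L)
  y <- sample(0:3, n, replace = TRUE)
  tgt <- winnowkan:::prepare_target(m, y)
  lossfun <- function(model) {
    out <- winnowkan:::kan_forward_cached(X, model)$out
    out <- winnowkan:::ordinal_head(out[, 1], model$head_bias)
    winnowkan:::loss_and_grad("ordinal", out, tgt)$loss
  }
  fw <- winnowkan:::kan_forward_cached(X, m)
  out <- winnowkan:::ordinal_head(fw$out[, 1], m$head_bias)
  gOut <- winnowkan:::loss_and_grad("ordinal", out, tgt)$grad
  ord <- order(m$head_bias, decreasing = TRUE)
  ghead <- numeric(length(m$head_bias)); ghead[ord] <- colSums(gOut)
  gOut <- matrix(rowSums(gOut), ncol = 1L)
  grads <- list()
  for (l in 2:1) {
    gr <- winnowkan:::layer_backward(m$layers[[l]], fw$caches[[l]], gOut,
                                     need_gx = l > 1L)
    grads[[l]] <- gr
    gOut <- gr$gX
  }
  eps <- 1e-6
  numgrad <- function(get, set) {
    th <- get(m)
    gn <- array(0, dim = dim(th))
    for (ii in seq_along(th)) {
      t1 <- th; t1[ii] <- t1[ii] + eps
      t2 <- th; t2[ii] <- t2[ii] - eps
      gn[ii] <- (lossfun(set(m, t1)) - lossfun(set(m, t2))) / (2 * eps)
    }
    gn
  }
  for (l in 1:2) {
    expect_equal(
      grads[[l]]$gWb,
      numgrad(function(m) m$layers[[l]]$Wb,
              function(m, v) { m$layers[[l]]$Wb <- v; m }),
      tolerance = 1e-6)
    expect_equal(
      grads[[l]]$gWs,
      numgrad(function(m) m$layers[[l]]$Ws,
              function(m, v) { m$layers[[l]]$Ws <- v; m }),
      tolerance = 1e-6)
    expect_equal(
      grads[[l]]$gC,
      numgrad(function(m) m$layers[[l]]$C,
              function(m, v) { m$layers[[l]]$C <- v; m }),
      tolerance = 1e-6)
  }
  gh <- numeric(length(m$head_bias))
  for (ii in seq_along(gh)) {
    m1 <- m; m1$head_bias[ii] <- m1$head_bias[ii] + eps
    m2 <- m; m2$head_bias[ii] <- m2$head_bias[ii] - eps
    gh[ii] <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
  }
  expect_equal(as.vector(ghead), gh, tolerance = 1e-6)
})

test_that("training descends on a learnable linear signal", {
  set.seed(75)
  n <- 160L
  X <- matrix(runif(n * 3L, 0, 2), n, 3L)
  Y <- cbind(0.3 * X[, 1] - 0.2 * X[, 2] + 0.1,
             0.5 * X[, 3] + 0.05 * X[, 1])
  m <- init_model(c(3, 4, 2), task = "coordinates", seed = 3)
  cfg <- train_config(epochs = 60L, batch_size = 32L, learning_rate = 5e-3,
                      seed = 1L, grid_update_epochs = integer(0),
                      weight_decay = 0)
  tr <- train_kan(m, X, Y, cfg)
  expect_lt(tail(tr$history, 1), 0.25 * tr$history[1])
  expect_true(all(is.finite(tr$history)))
})

test_that("a zero learning rate leaves parameters and loss untouched", {
  set.seed(85)
  X <- matrix(runif(60L, 0, 1), 20L, 3L)
  Y <- matrix(runif(40L), 20L, 2L)
  m <- init_model(c(3, 2), task = "coordinates", seed = 5)
  cfg <- train_config(epochs = 5L, batch_size = 8L, learning_rate = 0,
                      seed = 2L, grid_update_epochs = integer(0))
  tr <- train_kan(m, X, Y, cfg)
  expect_identical(tr$model$layers, m$layers)
  expect_equal(diff(range(tr$history)), 0)
})

test_that("training is bit-deterministic under a fixed seed", {
  set.seed(95)
  X <- matrix(runif(100L, 0, 2), 25L, 4L)
  y <- sample(0:2, 25L, replace = TRUE)
  run <- function() {
    m <- init_model(c(4, 3), task = "categorical", n_classes = 3, seed = 11)
    cfg <- train_config(epochs = 8L, batch_size = 8L, learning_rate = 3e-3,
                        seed = 4L, grid_update_epochs = c(1L, 4L))
    train_kan(m, X, y, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model, b$model)
})

test_that("training aborts with the offending epoch on non-finite loss", {
  set.seed(105)
  X <- matrix(runif(60L, 0, 2), 20L, 3L)
  Y <- matrix(runif(40L, 0, 1e4), 20L, 2L)
  m <- init_model(c(3, 2), task = "coordinates", seed = 1)
  cfg <- train_config(epochs = 20L, batch_size = 8L, learning_rate = 1e12,
                      seed = 1L, grid_update_epochs = integer(0),
                      optimizer = "sgd", weight_decay = 0)
  expect_error(train_kan(m, X, Y, cfg), "epoch")
})

test_that("grid updates preserve spline outputs up to the refit residual", {
  set.seed(115)
  m <- random_model(c(4, 3, 2), task = "coordinates", seed = 8)
  X <- matrix(runif(200L, 0, 3), 50L, 4L)
  before <- winnowkan:::kan_layer_inputs(X, m)
  res <- kan_update_grids(m, X)
  expect_true(all(res$diagnostics$refit_rms >= 0))
  # recompute the change in layer-1 spline outputs independently: it must
  # equal the reported refit residual per node
  la_old <- m$layers[[1]]; la_new <- res$model$layers[[1]]
  K <- la_old$G + la_old$kappa
  for (i in seq_len(la_old$in_dim)) {
    s <- before[[1]][, i]
    g_old <- grid_spec(la_old$knots[, i], la_old$G, la_old$kappa, la_old$epsilon)
    g_new <- grid_spec(la_new$knots[, i], la_new$G, la_new$kappa, la_new$epsilon)
    sp_old <- bspline_design(s, g_old) %*% t(matrix(la_old$C[, i, ], 3L, K))
    sp_new <- bspline_design(s, g_new) %*% t(matrix(la_new$C[, i, ], 3L, K))
    rms <- sqrt(mean((sp_new - sp_old)^2))
    want <- res$diagnostics$refit_rms[res$diagnostics$layer == 1 &
                                        res$diagnostics$node == i]
    expect_equal(rms, want, tolerance = 1e-10)
  }
  # constant input nodes are skipped untouched
  Xc <- X; Xc[, 2] <- 1.5
  res2 <- kan_update_grids(m, Xc)
  expect_identical(res2$model$layers[[1]]$knots[, 2], m$layers[[1]]$knots[, 2])
})

test_that("mid-training grid updates do not derail the loss", {
  set.seed(125)
  n <- 120L
  X <- matrix(runif(n * 3L, 0, 2), n, 3L)
  Y <- cbind(0.4 * X[, 1], 0.3 * X[, 2] - 0.1 * X[, 3])
  m <- init_model(c(3, 2), task = "coordinates", seed = 6)
  cfg <- train_config(epochs = 30L, batch_size = 32L, learning_rate = 5e-3,
                      seed = 3L, grid_update_epochs = c(1L, 5L, 10L),
                      weight_decay = 0)
  tr <- train_kan(m, X, Y, cfg)
  expect_true(all(is.finite(tr$history)))
  expect_lt(tail(tr$history, 1), tr$history[1])
})
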