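# KAN model structure and forward pass.  Edges carry phi(x) = w_b silu(x)
# + w_s spline(x) (optionally wrapped in a ReLU); nodes sum incoming edge
# outputs.  Within a layer all edges leaving the same input node share one
# knot vector: grid updates pool exactly the same samples (the source
# node's values) for every such edge, so their grids coincide by
# construction and are stored once per input node.

#' SiLU activation
#'
#' `silu(x) = x / (1 + exp(-x))`, evaluated through the logistic CDF for
#' numerical stability at large `|x|`.
#'
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
silu <- function(x) x * stats::plogis(x)

# d/dx silu(x) = sigma(x) (1 + x (1 - sigma(x)))
silu_prime <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

relu <- function(x) pmax(x, 0)

#' Single edge activation
#'
#' `phi(x) = w_b * silu(x) + w_s * spline(x)`; with `use_relu = TRUE` the
#' whole sum is passed through `max(0, .)` (the ReLU-augmented variant).
#'
#' @param x numeric vector.
#' @param params an [edge_params()].
#' @param use_relu logical; apply the ReLU wrapper.
#' @return numeric vector.
#' @export
edge_activation <- function(x, params, use_relu = FALSE) {
  z <- params$w_b * silu(x) + params$w_s * evaluate_spline(x, params)
  if (use_relu) relu(z) else z
}

# One KAN layer.  Wb, Ws: out_dim x in_dim weight banks; C: array
# (out_dim, in_dim, K) of spline coefficients; knots: (G + 2 kappa + 1) x
# in_dim, one knot vector per input node.
new_kan_layer <- function(in_dim, out_dim, G = 5L, kappa = 3L, epsilon = 0.02,
                          use_relu = TRUE, lo = -1, hi = 1) {
  in_dim <- as.integer(in_dim); out_dim <- as.integer(out_dim)
  G <- as.integer(G); kappa <- as.integer(kappa)
  K <- G + kappa
  h <- (hi - lo) / G
  kn <- seq(lo - kappa * h, hi + kappa * h, length.out = G + 2L * kappa + 1L)
  # Fan-in scaling keeps node sums O(1) at any width: w_b is positive (so
  # no ReLU edge is born dead on non-negative expression inputs) and its
  # terms add coherently, hence the 1/in_dim scale; w_s starts equal on
  # every edge so no gene is favoured before training, and its spline
  # terms have random signs, hence 1/sqrt(in_dim).
  structure(list(
    in_dim = in_dim, out_dim = out_dim, G = G, kappa = kappa,
    epsilon = epsilon, use_relu = isTRUE(use_relu),
    knots = matrix(kn, length(kn), in_dim),
    Wb = matrix(stats::runif(out_dim * in_dim, 0.5, 1.5) / in_dim,
                out_dim, in_dim),
    Ws = matrix(1 / sqrt(in_dim), out_dim, in_dim),
    C = array(stats::rnorm(out_dim * in_dim * K, sd = 0.1),
              c(out_dim, in_dim, K))
  ), class = "kan_layer")
}

# Extract one edge's parameters as an edge_params object (shared grid of
# its input node).
layer_edge <- function(layer, o, i) {
  g <- grid_spec(layer$knots[, i], layer$G, layer$kappa, layer$epsilon)
  edge_params(layer$Wb[o, i], layer$Ws[o, i], layer$C[o, i, ], g)
}

n_bases_layer <- function(layer) layer$G + layer$kappa

# Forward pass through one layer for a batch.
# Returns list(out, cache) where cache holds everything backward needs.
layer_forward_mat <- function(X, layer, apply_relu = layer$use_relu,
                              want_cache = FALSE, want_deriv = FALSE) {
  n <- nrow(X); p_in <- layer$in_dim; p_out <- layer$out_dim
  if (ncol(X) != p_in) {
    stop(sprintf("input has %d columns but layer expects %d", ncol(X), p_in))
  }
  K <- n_bases_layer(layer)
  Xt <- t(X)                                          # p_in x n
  des <- bsd_core_t(Xt, layer$knots, layer$kappa, deriv = want_deriv)
  SILt <- silu(Xt)
  if (p_out == 1L) {
    # fast path for the (typically very wide) single-node Winnow layer:
    # everything stays a p_in x n matrix, length-p_in vectors broadcast
    # down columns natively
    Cm <- matrix(layer$C[1L, , ], p_in, K)            # p_in x K
    SPt <- des$Bt[[1L]] * Cm[, 1L]
    for (k in 1L + seq_len(K - 1L)) SPt <- SPt + des$Bt[[k]] * Cm[, k]
    Zt <- SILt * layer$Wb[1L, ] + SPt * layer$Ws[1L, ]
    At <- if (apply_relu) pmax(Zt, 0) else Zt
    out <- matrix(colSums(At), n, 1L)
    res <- list(out = out)
    if (want_cache) {
      res$cache <- list(Xt = Xt, SILt = SILt, Bt = des$Bt, dBt = des$dBt,
                        Zt = Zt, SPt = SPt, Cm = Cm,
                        relu = apply_relu, fast = TRUE)
    }
    return(res)
  }
  # general path: per-input-node loop (layers past the Winnow layer are
  # narrow, so these loops are short)
  SIL <- t(SILt)
  Barr <- array(0, c(n, K, p_in))
  for (k in seq_len(K)) Barr[, k, ] <- t(des$Bt[[k]])
  dBarr <- NULL
  if (want_deriv) {
    dBarr <- array(0, c(n, K, p_in))
    for (k in seq_len(K)) dBarr[, k, ] <- t(des$dBt[[k]])
  }
  Z <- array(0, c(n, p_out, p_in))
  SP <- array(0, c(n, p_out, p_in))
  for (i in seq_len(p_in)) {
    Ci <- matrix(layer$C[, i, ], p_out, K)
    spi <- matrix(Barr[, , i], n, K) %*% t(Ci)        # n x p_out
    SP[, , i] <- spi
    Z[, , i] <- SIL[, i] %o% layer$Wb[, i] +
      spi * rep(layer$Ws[, i], each = n)
  }
  A <- if (apply_relu) pmax(Z, 0) else Z
  out <- rowSums(A, dims = 2L)
  if (p_out == 1L) out <- matrix(out, n, 1L)
  res <- list(out = out)
  if (want_cache) {
    res$cache <- list(X = X, SIL = SIL, B = Barr, dB = dBarr,
                      Z = Z, SP = SP, relu = apply_relu, fast = FALSE)
  }
  res
}

# Backward pass through one layer: gOut is dLoss/dOut (n x p_out).
# Returns gradients for Wb, Ws, C and the input (for chaining).
layer_backward <- function(layer, cache, gOut, need_gx = TRUE) {
  p_in <- layer$in_dim; p_out <- layer$out_dim
  K <- n_bases_layer(layer)
  if (isTRUE(cache$fast)) {
    # p_out == 1 fast path: mirror of the forward fast path (p_in x n)
    n <- ncol(cache$Xt)
    dZt <- matrix(gOut[, 1L], p_in, n, byrow = TRUE)
    if (cache$relu) dZt <- dZt * (cache$Zt > 0)
    gWb <- matrix(rowSums(dZt * cache$SILt), 1L, p_in)
    gWs <- matrix(rowSums(dZt * cache$SPt), 1L, p_in)
    gCm <- matrix(0, p_in, K)
    for (k in seq_len(K)) gCm[, k] <- rowSums(cache$Bt[[k]] * dZt)
    gC <- array(gCm * layer$Ws[1L, ], c(1L, p_in, K))
    gX <- NULL
    if (need_gx) {
      dSPt <- cache$dBt[[1L]] * cache$Cm[, 1L]
      for (k in 1L + seq_len(K - 1L)) dSPt <- dSPt + cache$dBt[[k]] * cache$Cm[, k]
      gXt <- dZt * layer$Wb[1L, ] * silu_prime(cache$Xt) +
        dZt * dSPt * layer$Ws[1L, ]
      gX <- t(gXt)
    }
    return(list(gWb = gWb, gWs = gWs, gC = gC, gX = gX))
  }
  n <- nrow(cache$X)
  gWb <- matrix(0, p_out, p_in)
  gWs <- matrix(0, p_out, p_in)
  gC <- array(0, c(p_out, p_in, K))
  gX <- if (need_gx) matrix(0, n, p_in) else NULL
  silp <- if (need_gx) silu_prime(cache$X) else NULL
  for (i in seq_len(p_in)) {
    dZi <- gOut
    if (cache$relu) dZi <- dZi * (matrix(cache$Z[, , i], n, p_out) > 0)
    SPi <- matrix(cache$SP[, , i], n, p_out)
    Bi <- matrix(cache$B[, , i], n, K)
    gWb[, i] <- crossprod(dZi, cache$SIL[, i])
    gWs[, i] <- colSums(dZi * SPi)
    gC[, i, ] <- (crossprod(dZi, Bi)) * layer$Ws[, i]
    if (need_gx) {
      Ci <- matrix(layer$C[, i, ], p_out, K)
      dSPi <- matrix(cache$dB[, , i], n, K) %*% t(Ci) # n x p_out
      gX[, i] <- (dZi %*% layer$Wb[, i]) * silp[, i] +
        rowSums(dZi * dSPi * rep(layer$Ws[, i], each = n))
    }
  }
  list(gWb = gWb, gWs = gWs, gC = gC, gX = gX)
}

#' Forward pass through one KAN layer
#'
#' Output node `k` is the sum over input nodes `j` of the edge activations
#' `phi_{k,j}(x_j)` -- KAN nodes perform addition only.
#'
#' @param x numeric vector of length `in_dim`, or a matrix with one object
#'   per row.
#' @param layer a layer from a [init_model()] model.
#' @param apply_relu logical; defaults to the layer's own setting.
#' @return numeric vector of length `out_dim` (or a matrix for matrix
#'   input).
#' @export
layer_forward <- function(x, layer, apply_relu = layer$use_relu) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  out <- layer_forward_mat(X, layer, apply_relu = apply_relu)$out
  if (vec) as.vector(out) else out
}

out_dim_for_task <- function(task, n_classes) {
  switch(task,
         coordinates = 2L,
         ordinal = 1L,
         categorical = as.integer(n_classes),
         stop("unknown task: ", task))
}

#' Initialize a KAN model
#'
#' Builds an `L`-layer KAN with the given node dimensions.  Every layer's
#' edges start on the uniform grid over `[-1, 1]`; spline weights start
#' equal (fan-in scaled) so gene importances are unbiased at epoch zero,
#' base weights are positive fan-in-scaled draws, and spline coefficients
#' are small Gaussian noise.  The same seed reproduces the model exactly.
#'
#' @param dims integer vector `[p_1, ..., p_L]` of node counts per layer,
#'   the first entry being the input (gene) dimension.  For
#'   `task = "coordinates"` the last entry must be 2; for `"ordinal"` it
#'   must be 1 (the shared CORAL score); for `"categorical"` it must equal
#'   `n_classes`.
#' @param task one of `"coordinates"`, `"ordinal"`, `"categorical"`.
#' @param n_classes number of classes (ordinal / categorical tasks).
#' @param G,kappa,epsilon grid hyperparameters shared by all edges.
#' @param use_relu logical; use the ReLU-augmented edge activation on all
#'   layers except the last (the head is always exempt so coordinates and
#'   logits may be negative).
#' @param seed integer; fixes the parameter draw.
#' @return an object of class `kan_model`.
#' @export
init_model <- function(dims, task = c("coordinates", "ordinal", "categorical"),
                       n_classes = NULL, G = 5L, kappa = 3L, epsilon = 0.02,
                       use_relu = TRUE, seed = 1L) {
  task <- match.arg(task)
  dims <- as.integer(dims)
  if (length(dims) < 2L || anyNA(dims) || any(dims < 1L)) {
    stop("dims must be >= 2 positive integers")
  }
  if (task != "coordinates") {
    if (is.null(n_classes) || n_classes < 2L) {
      stop("n_classes >= 2 required for ordinal/categorical tasks")
    }
    n_classes <- as.integer(n_classes)
  }
  want_out <- out_dim_for_task(task, n_classes)
  if (dims[length(dims)] != want_out) {
    stop(sprintf("output dim must be %d for task '%s', got %d",
                 want_out, task, dims[length(dims)]))
  }
  set.seed(seed)
  L <- length(dims) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- new_kan_layer(dims[l], dims[l + 1L], G = G, kappa = kappa,
                                 epsilon = epsilon, use_relu = use_relu)
  }
  head_bias <- NULL
  if (task == "ordinal") {
    head_bias <- seq(0.5, -0.5, length.out = n_classes - 1L)
  }
  structure(list(dims = dims, task = task, n_classes = n_classes,
                 use_relu = isTRUE(use_relu), layers = layers,
                 head_bias = head_bias, seed = as.integer(seed)),
            class = "kan_model")
}

# Ordinal head: cumulative logit r = score + b_(r) with biases sorted
# non-increasing, so sigma(logit) is monotone in r by construction.
ordinal_head <- function(score, head_bias) {
  b <- sort(head_bias, decreasing = TRUE)
  sweep(matrix(score, length(score), length(b)), 2L, b, "+")
}

#' Forward pass through a full KAN model
#'
#' Row-wise composition of the layer maps.  The final layer never applies
#' the ReLU wrapper.  For the ordinal task the scalar network score is
#' expanded by the `n_classes - 1` head biases (sorted non-increasing)
#' into cumulative logits; for the categorical task the output columns are
#' class logits; for coordinates the output is the raw `n x 2` prediction.
#'
#' @param X numeric matrix, objects by genes; gene count must equal
#'   `dims[1]`.
#' @param model a [init_model()] model.
#' @return numeric matrix of predictions / logits.
#' @export
kan_forward <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != model$dims[1L]) {
    stop(sprintf("model expects %d genes, got %d columns",
                 model$dims[1L], ncol(X)))
  }
  L <- length(model$layers)
  H <- X
  for (l in seq_len(L)) {
    ar <- model$layers[[l]]$use_relu && l < L
    H <- layer_forward_mat(H, model$layers[[l]], apply_relu = ar)$out
  }
  if (model$task == "ordinal") {
    H <- ordinal_head(H[, 1L], model$head_bias)
  }
  H
}

# Forward pass keeping per-layer caches (training path).  Basis
# derivatives are only materialized where backprop chains through the
# layer's input (every layer but the first).
kan_forward_cached <- function(X, model) {
  L <- length(model$layers)
  caches <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    ar <- model$layers[[l]]$use_relu && l < L
    r <- layer_forward_mat(H, model$layers[[l]], apply_relu = ar,
                           want_cache = TRUE, want_deriv = l > 1L)
    caches[[l]] <- r$cache
    H <- r$out
  }
  list(out = H, caches = caches)
}

# Inputs seen by each layer on a full forward pass (for grid updates).
kan_layer_inputs <- function(X, model) {
  L <- length(model$layers)
  ins <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    ins[[l]] <- H
    ar <- model$layers[[l]]$use_relu && l < L
    H <- layer_forward_mat(H, model$layers[[l]], apply_relu = ar)$out
  }
  ins
}

#' @export
print.kan_model <- function(x, ...) {
  cat(sprintf("KAN model [%s], task = %s%s, %s edge activations\n",
              paste(x$dims, collapse = ", "), x$task,
              if (!is.null(x$n_classes)) sprintf(" (%d classes)", x$n_classes) else "",
              if (x$use_relu) "ReLU-augmented" else "plain"))
  invisible(x)
}
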