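# Minibatch training of a KAN model: Adam on the task loss, with optional
# mid-training grid updates (adaptive knots recomputed from the inputs each
# layer actually sees, followed by a least-squares coefficient refit that
# preserves the spline outputs on the update batch).

#' Training configuration
#'
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer; fixes batch shuffling (and anything else stochastic
#'   in the loop).
#' @param grid_update_epochs integer vector of epochs after which every
#'   layer re-derives its knot grids from the inputs it saw and refits the
#'   spline coefficients.  Default `c(1, 10, 25, 50)`, none thereafter:
#'   the epoch-1 update moves the initial `[-1, 1]` grids onto the actual
#'   input range (log-expression values are non-negative), without which
#'   the spline parts see zero gradient early on.
#' @param class_weights optional per-class weight vector (see
#'   [compute_class_weights()]); objects inherit their class weight in the
#'   ordinal and categorical losses.
#' @param optimizer `"adam"` or `"sgd"` (plain gradient descent with
#'   momentum `beta1`).  Adam's per-coordinate normalization moves every
#'   weight at the full step size no matter how small its gradient, which
#'   lets the spline weights of pure-noise genes diffuse upward; SGD keeps
#'   updates proportional to the true gradient and so preserves the
#'   signal/noise separation in `w_s` that the Winnow selector reads.
#' @param weight_decay decoupled (AdamW-style) L2 decay applied to all
#'   layer weights each step (head biases exempt).  Decay starves the
#'   spline weights of genes that carry no signal, sharpening the
#'   separation the Winnow selector reads off `w_s`.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer
#'   (`beta1` doubles as the SGD momentum).
#' @param verbose print the loss every 10 epochs.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 128L,
                         learning_rate = 1e-3, seed = 1L,
                         grid_update_epochs = c(1L, 10L, 25L, 50L),
                         class_weights = NULL,
                         optimizer = c("adam", "sgd"), weight_decay = 1e-2,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         verbose = FALSE) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  optimizer <- match.arg(optimizer)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 grid_update_epochs = as.integer(grid_update_epochs),
                 class_weights = class_weights, optimizer = optimizer,
                 weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Adam state for one parameter array.
adam_new <- function(theta) list(m = array(0, dim = dim(theta) %||% length(theta)),
                                 v = array(0, dim = dim(theta) %||% length(theta)))

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(theta, g, st, cfg, t, decay = TRUE) {
  if (decay && cfg$weight_decay > 0) {
    theta <- theta * (1 - cfg$learning_rate * cfg$weight_decay)
  }
  if (cfg$optimizer == "sgd") {
    st$m <- cfg$beta1 * st$m + g
    theta <- theta - cfg$learning_rate * st$m
    return(list(theta = theta, st = st))
  }
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g * g
  mhat <- st$m / (1 - cfg$beta1^t)
  vhat <- st$v / (1 - cfg$beta2^t)
  theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  list(theta = theta, st = st)
}

#' Re-derive all grids of a model from data
#'
#' Runs a full forward pass on `X`, and for every layer and input node
#' rebuilds the knot grid from the node's observed values
#' ([update_grid()] policy) and refits the spline coefficients of all
#' edges leaving that node by least squares against their previous
#' outputs.  Input nodes with a degenerate (constant) value range are left
#' untouched.
#'
#' @param model a `kan_model`.
#' @param X training matrix (objects x genes).
#' @return list with the updated `model` and `diagnostics`, a data frame
#'   with one row per updated node carrying the refit RMS residual and the
#'   RMS change in spline output on the batch.
#' @export
kan_update_grids <- function(model, X) {
  ins <- kan_layer_inputs(as.matrix(X), model)
  diag_rows <- list()
  for (l in seq_along(model$layers)) {
    layer <- model$layers[[l]]
    Xl <- ins[[l]]
    n <- nrow(Xl)
    K <- n_bases_layer(layer)
    for (i in seq_len(layer$in_dim)) {
      s <- Xl[, i]
      if (max(s) - min(s) <= 0) next  # constant node: keep previous grid
      interior <- blend_interior_knots(s, layer$G, layer$epsilon)
      h <- (max(s) - min(s)) / layer$G
      kn <- c(interior[1L] - h * (layer$kappa:1), interior,
              interior[layer$G + 1L] + h * seq_len(layer$kappa))
      Bold <- matrix(bsd_core(matrix(s, ncol = 1L),
                              matrix(layer$knots[, i], ncol = 1L),
                              layer$kappa)$B, n, K)
      Bnew <- matrix(bsd_core(matrix(s, ncol = 1L), matrix(kn, ncol = 1L),
                              layer$kappa)$B, n, K)
      Cold <- matrix(layer$C[, i, ], layer$out_dim, K)
      Yold <- Bold %*% t(Cold)                      # n x out_dim
      Cnew <- ls_minnorm(Bnew, Yold, warn = FALSE)  # K x out_dim
      resid <- Bnew %*% Cnew - Yold
      layer$knots[, i] <- kn
      layer$C[, i, ] <- t(Cnew)
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        layer = l, node = i,
        refit_rms = sqrt(mean(resid^2)),
        output_change_rms = sqrt(mean(resid^2)))
    }
    model$layers[[l]] <- layer
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(layer = integer(), node = integer(),
               refit_rms = numeric(), output_change_rms = numeric())
  list(model = model, diagnostics = diagnostics)
}

prepare_target <- function(model, Y) {
  if (model$task == "coordinates") {
    Y <- as.matrix(Y)
    if (ncol(Y) != 2L) stop("coordinates task needs an n x 2 target")
    list(Y = Y)
  } else if (model$task == "ordinal") {
    enc <- coral_encode(Y, model$n_classes)
    list(extended = enc$extended, labels = as.integer(Y))
  } else {
    labels <- as.integer(Y)
    if (any(labels < 0L) || any(labels >= model$n_classes)) stop("label out of range")
    list(labels = labels)
  }
}

subset_target <- function(model, tgt, idx) {
  if (model$task == "coordinates") list(Y = tgt$Y[idx, , drop = FALSE])
  else if (model$task == "ordinal") list(extended = tgt$extended[idx, , drop = FALSE],
                                         labels = tgt$labels[idx])
  else list(labels = tgt$labels[idx])
}

#' Train a KAN model
#'
#' Minibatch Adam on the task loss.  After each epoch listed in
#' `cfg$grid_update_epochs` the knot grids are re-derived from the full
#' training matrix and the spline coefficients refitted
#' ([kan_update_grids()]).  Training aborts with a diagnostic naming the
#' epoch if the loss turns non-finite.
#'
#' @param model a [init_model()] model.
#' @param X numeric training matrix (objects x genes), already
#'   preprocessed.
#' @param Y targets: `n x 2` matrix (coordinates) or 0-based integer
#'   labels (ordinal / categorical).
#' @param cfg a [train_config()].
#' @return list with the trained `model` and `history`, the per-epoch
#'   training loss.
#' @export
train_kan <- function(model, X, Y, cfg = train_config()) {
  stopifnot(inherits(model, "kan_model"), inherits(cfg, "train_config"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  if (ncol(X) != model$dims[1L]) {
    stop(sprintf("model expects %d genes, got %d columns",
                 model$dims[1L], ncol(X)))
  }
  n <- nrow(X)
  tgt <- prepare_target(model, Y)
  w_obj <- NULL
  if (model$task != "coordinates" && !is.null(cfg$class_weights)) {
    w_obj <- cfg$class_weights[tgt$labels + 1L]
  }

  set.seed(cfg$seed)
  L <- length(model$layers)
  st <- lapply(model$layers, function(la)
    list(Wb = adam_new(la$Wb), Ws = adam_new(la$Ws), C = adam_new(la$C)))
  st_head <- if (model$task == "ordinal") adam_new(model$head_bias) else NULL

  history <- numeric(cfg$epochs)
  t_adam <- 0L
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s0 in starts) {
      b <- idx[s0:min(s0 + cfg$batch_size - 1L, n)]
      Xb <- X[b, , drop = FALSE]
      fw <- kan_forward_cached(Xb, model)
      out <- fw$out
      ghead <- NULL
      if (model$task == "ordinal") {
        out <- ordinal_head(out[, 1L], model$head_bias)
      }
      lg <- loss_and_grad(model$task, out, subset_target(model, tgt, b),
                          if (is.null(w_obj)) NULL else w_obj[b])
      gOut <- lg$grad
      if (model$task == "ordinal") {
        # chain through the head: score gets the row sums, sorted biases the
        # column sums mapped back to their raw positions
        ord <- order(model$head_bias, decreasing = TRUE)
        ghead <- numeric(length(model$head_bias))
        ghead[ord] <- colSums(gOut)
        gOut <- matrix(rowSums(gOut), ncol = 1L)
      }
      t_adam <- t_adam + 1L
      for (l in rev(seq_len(L))) {
        gr <- layer_backward(model$layers[[l]], fw$caches[[l]], gOut,
                             need_gx = l > 1L)
        up <- adam_step(model$layers[[l]]$Wb, gr$gWb, st[[l]]$Wb, cfg, t_adam)
        model$layers[[l]]$Wb <- up$theta; st[[l]]$Wb <- up$st
        up <- adam_step(model$layers[[l]]$Ws, gr$gWs, st[[l]]$Ws, cfg, t_adam)
        model$layers[[l]]$Ws <- up$theta; st[[l]]$Ws <- up$st
        up <- adam_step(model$layers[[l]]$C, gr$gC, st[[l]]$C, cfg, t_adam)
        model$layers[[l]]$C <- up$theta; st[[l]]$C <- up$st
        gOut <- gr$gX
      }
      if (!is.null(ghead)) {
        up <- adam_step(model$head_bias, ghead, st_head, cfg, t_adam,
                        decay = FALSE)
        model$head_bias <- up$theta; st_head <- up$st
      }
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    history[ep] <- ep_loss / n
    if (!is.finite(history[ep])) {
      stop(sprintf("non-finite training loss at epoch %d; lower the learning rate or inspect the inputs", ep))
    }
    if (ep %in% cfg$grid_update_epochs) {
      model <- kan_update_grids(model, X)$model
    }
    if (cfg$verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  loss %.6f", ep, history[ep]))
    }
  }
  list(model = model, history = history)
}
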