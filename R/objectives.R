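# Task losses: CORAL rank-consistent ordinal loss with class weighting,
# weighted softmax cross-entropy, and coordinate MSE, plus the ordinal
# label encoding/decoding they rely on.  Labels are 0-based integers
# throughout (0 .. K_c - 1).

# Numerically stable binary cross-entropy with logits.
bce_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' Extended binary encoding of ordinal labels (CORAL)
#'
#' Label `y` in `0 .. K_c - 1` becomes a binary vector of length
#' `K_c - 1` whose entry `r` is 1 iff `y > r - 1` (i.e. a block of ones
#' followed by zeros).
#'
#' @param labels integer vector of 0-based ordinal labels.
#' @param n_classes number of ordered classes `K_c`.
#' @return object of class `ordinal_encoding` with fields `n_classes` and
#'   `extended` (an `n x (K_c - 1)` binary matrix).
#' @export
coral_encode <- function(labels, n_classes) {
  n_classes <- as.integer(n_classes)
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= n_classes)) {
    stop(sprintf("labels must lie in 0 .. %d", n_classes - 1L))
  }
  R <- n_classes - 1L
  ext <- matrix(0, length(labels), R)
  for (r in seq_len(R)) ext[, r] <- as.numeric(labels >= r)
  structure(list(n_classes = n_classes, extended = ext),
            class = "ordinal_encoding")
}

#' CORAL rank-consistent ordinal loss
#'
#' Weighted mean over objects of the summed binary logistic losses across
#' the `K_c - 1` cumulative tasks.  With all-zero logits and unit weights
#' the per-object loss is `(K_c - 1) * log(2)`.
#'
#' @param cum_logits `n x (K_c - 1)` matrix of cumulative logits.
#' @param enc a [coral_encode()] result for the same objects.
#' @param spot_weights non-negative per-object weights (default all 1).
#' @return scalar loss.
#' @export
coral_loss <- function(cum_logits, enc, spot_weights = NULL) {
  stopifnot(inherits(enc, "ordinal_encoding"))
  cum_logits <- as.matrix(cum_logits)
  if (any(!is.finite(cum_logits))) stop("non-finite logits")
  if (!identical(dim(cum_logits), dim(enc$extended))) {
    stop("logit and encoding dimensions disagree")
  }
  n <- nrow(cum_logits)
  w <- if (is.null(spot_weights)) rep(1, n) else as.numeric(spot_weights)
  if (length(w) != n || any(w < 0)) stop("spot_weights must be n non-negative values")
  per_obj <- rowSums(bce_logits(cum_logits, enc$extended))
  sum(w * per_obj) / sum(w)
}

#' Decode cumulative logits to ordinal labels
#'
#' Predicted label = number of cumulative probabilities
#' `sigma(logit) > 0.5`, i.e. the count of positive logits.  Any count in
#' `0 .. K_c - 1` is a valid label, so decoding is rank-consistent by
#' construction with the shared-score head.
#'
#' @param cum_logits `n x (K_c - 1)` matrix.
#' @return integer vector of 0-based labels.
#' @export
coral_decode <- function(cum_logits) {
  cum_logits <- as.matrix(cum_logits)
  as.integer(rowSums(cum_logits > 0))
}

#' Inverse-frequency class weights
#'
#' Weight for class `l` is proportional to the inverse of its frequency
#' `n_l / N`, normalized so the observed classes' weights average 1.  A
#' declared class with no objects gets weight 0 with a warning.
#'
#' @param labels integer vector of 0-based labels.
#' @param n_classes number of declared classes (default: max label + 1).
#' @return numeric vector of length `n_classes`; index `l + 1` is the
#'   weight of class `l`.  Each object inherits its class weight.
#' @export
compute_class_weights <- function(labels, n_classes = max(labels) + 1L) {
  labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    warning("declared class(es) with no objects receive weight 0: ",
            paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  w <- ifelse(counts > 0L, 1 / (counts / sum(counts)), 0)
  obs <- counts > 0L
  w[obs] <- w[obs] / mean(w[obs])
  w
}

# log-softmax by row, stabilized.
log_softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

#' Weighted softmax cross-entropy
#'
#' @param logits `n x K_c` matrix of class logits.
#' @param labels integer vector of 0-based labels.
#' @param weights optional per-object non-negative weights.
#' @return scalar loss (weighted mean of per-object negative log
#'   likelihoods).
#' @export
weighted_cross_entropy <- function(logits, labels, weights = NULL) {
  logits <- as.matrix(logits)
  if (any(!is.finite(logits))) stop("non-finite logits")
  labels <- as.integer(labels)
  n <- nrow(logits)
  if (any(labels < 0L) || any(labels >= ncol(logits))) stop("label out of range")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  ls <- log_softmax(logits)
  nll <- -ls[cbind(seq_len(n), labels + 1L)]
  sum(w * nll) / sum(w)
}

#' Mean squared error for coordinate regression
#'
#' Mean over objects and both coordinate axes of the squared error.
#'
#' @param pred,truth `n x 2` matrices.
#' @return scalar.
#' @export
mse_loss <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch between pred and truth")
  mean((pred - truth)^2)
}

# --- loss + gradient dispatch used by the training loop ------------------

# target: list with task-specific fields; returns list(loss, grad) where
# grad is dLoss/d(network output matrix).  For ordinal, also gradient wrt
# head biases (sorted order) is folded in by the caller.
loss_and_grad <- function(task, out, target, w = NULL) {
  n <- nrow(out)
  if (task == "coordinates") {
    d <- out - target$Y
    list(loss = mean(d^2), grad = 2 * d / length(d))
  } else if (task == "ordinal") {
    ext <- target$extended
    ww <- if (is.null(w)) rep(1, n) else w
    p <- stats::plogis(out)
    per_obj <- rowSums(bce_logits(out, ext))
    list(loss = sum(ww * per_obj) / sum(ww),
         grad = (p - ext) * (ww / sum(ww)))
  } else {
    ww <- if (is.null(w)) rep(1, n) else w
    ls <- log_softmax(out)
    P <- exp(ls)
    nll <- -ls[cbind(seq_len(n), target$labels + 1L)]
    G <- P
    G[cbind(seq_len(n), target$labels + 1L)] <-
      G[cbind(seq_len(n), target$labels + 1L)] - 1
    list(loss = sum(ww * nll) / sum(ww), grad = G * (ww / sum(ww)))
  }
}
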