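# Evaluation metrics: distance errors and pairwise-distance Pearson
# correlation for coordinate prediction; top-1 / top-2 (adjacent-layer)
# accuracy for ordinal domain recovery; probability top-k for categorical
# labels.

#' Mean and median Euclidean distance error
#'
#' Per-object Euclidean distances between predicted and true 2D
#' coordinates, summarized by their mean and median (even `n`: midpoint
#' average).  Units are whatever the coordinates carry.
#'
#' @param pred,truth `n x 2` matrices.
#' @return named numeric vector `c(mean_de, median_de)`.
#' @export
distance_errors <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (nrow(pred) < 1L) stop("need at least one object")
  d <- sqrt(rowSums((pred - truth)^2))
  c(mean_de = mean(d), median_de = stats::median(d))
}

#' Pearson correlation of pairwise distances
#'
#' Pearson r between the `n(n-1)/2` unordered-pair Euclidean distances of
#' the predicted and the true coordinates: how well relative spatial
#' relationships are recovered, invariant to translation and uniform
#' scaling of either argument.  Zero variance in either distance vector is
#' undefined and returns `NaN` with a warning.
#'
#' @param pred,truth `n x 2` matrices, `n >= 3`.
#' @return scalar in `[-1, 1]` (or `NaN`).
#' @export
pairwise_distance_correlation <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (nrow(pred) < 3L) stop("need n >= 3 objects")
  dp <- as.vector(stats::dist(pred))
  dt <- as.vector(stats::dist(truth))
  if (stats::sd(dp) == 0 || stats::sd(dt) == 0) {
    warning("zero variance in a pairwise distance vector; correlation undefined")
    return(NaN)
  }
  stats::cor(dp, dt)
}

#' Top-1 and top-2 (adjacent) accuracy for ordinal labels
#'
#' Top-1 is the fraction of exactly correct predictions; top-2 the
#' fraction landing on the true label or a label adjacent to it in the
#' stated ordering (rank distance at most 1).
#'
#' @param pred_labels,truth label vectors (values of `ordering`).
#' @param ordering the ordered label levels, e.g. `0:6` or
#'   `c("L1", ..., "WM")`.
#' @return named numeric vector `c(top1, top2)`.
#' @export
topk_accuracy_ordinal <- function(pred_labels, truth, ordering) {
  rp <- match(pred_labels, ordering)
  rt <- match(truth, ordering)
  if (anyNA(rp) || anyNA(rt)) {
    bad <- unique(c(pred_labels[is.na(rp)], truth[is.na(rt)]))
    stop("label(s) not in ordering: ", paste(bad, collapse = ", "))
  }
  c(top1 = mean(rp == rt), top2 = mean(abs(rp - rt) <= 1L))
}

#' Top-k accuracy for categorical predictions
#'
#' Fraction of objects whose true class is among the `k` classes with the
#' highest predicted probability (ties broken by class index).
#'
#' @param probs `n x K_c` matrix of per-class probabilities (rows need not
#'   be exactly normalized; only the ordering matters).
#' @param truth 0-based integer labels.
#' @param k how many top classes count as a hit; `k <= K_c`.
#' @return scalar in `[0, 1]`.
#' @export
topk_accuracy_categorical <- function(probs, truth, k = 1L) {
  probs <- as.matrix(probs)
  k <- as.integer(k)
  if (k < 1L || k > ncol(probs)) stop("k must lie in 1 .. number of classes")
  truth <- as.integer(truth)
  hit <- vapply(seq_len(nrow(probs)), function(i) {
    ord <- order(-probs[i, ], seq_len(ncol(probs)))
    (truth[i] + 1L) %in% ord[seq_len(k)]
  }, logical(1L))
  mean(hit)
}

#' Assemble an evaluation report
#'
#' Computes the task-relevant metric set and returns it as a one-row data
#' frame that can be written as delimited text.
#'
#' @param task `"coordinates"`, `"ordinal"`, or `"categorical"`.
#' @param pred predictions: `n x 2` coordinates, ordinal labels, or a
#'   probability matrix.
#' @param truth ground truth matching `pred`.
#' @param ordering label ordering for the ordinal task.
#' @param path optional file; if given, the report is written as
#'   tab-delimited text.
#' @return data frame of metrics.
#' @export
evaluation_report <- function(task, pred, truth, ordering = NULL, path = NULL) {
  if (task == "coordinates") {
    de <- distance_errors(pred, truth)
    r <- pairwise_distance_correlation(pred, truth)
    rep <- data.frame(task = task, n_objects = nrow(as.matrix(pred)),
                      mean_de = de[["mean_de"]], median_de = de[["median_de"]],
                      pairwise_pearson = r)
  } else if (task == "ordinal") {
    if (is.null(ordering)) ordering <- sort(unique(c(pred, truth)))
    acc <- topk_accuracy_ordinal(pred, truth, ordering)
    rep <- data.frame(task = task, n_objects = length(truth),
                      top1 = acc[["top1"]], top2 = acc[["top2"]])
  } else {
    top1 <- topk_accuracy_categorical(pred, truth, 1L)
    top2 <- topk_accuracy_categorical(pred, truth, min(2L, ncol(as.matrix(pred))))
    rep <- data.frame(task = task, n_objects = length(truth),
                      top1 = top1, top2 = top2)
  }
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}
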