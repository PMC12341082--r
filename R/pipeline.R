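# End-to-end orchestration: preprocessing, stage-1 fit + Winnow selection,
# stage-2 refit on the reduced gene set, and query prediction.

#' Preprocess a raw count matrix
#'
#' Drops genes detected (count > 0) in fewer than `min_cells` objects and
#' genes whose name starts with a mitochondrial prefix (case-insensitive);
#' scales every object's counts to a common library size (the median of
#' per-object totals over the kept genes); applies `log(x + 1)`.  The
#' returned parameters suffice to replay the transform on a query.
#'
#' @param counts non-negative objects x genes count matrix.
#' @param gene_names gene names (default: column names).
#' @param mito_prefixes prefixes marking mitochondrial genes; matched
#'   case-insensitively at the start of the gene name.
#' @param min_cells minimum number of objects a gene must be detected in.
#' @return list with `X` (the normalized log matrix) and `params` (class
#'   `preprocess_params`).
#' @export
preprocess_counts <- function(counts, gene_names = colnames(counts),
                              mito_prefixes = c("MT-", "mt-"),
                              min_cells = 3L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(gene_names)) gene_names <- default_gene_names(ncol(counts))
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  detected <- colSums(counts > 0)
  pref <- unique(tolower(mito_prefixes))
  is_mito <- Reduce(`|`, lapply(pref, function(p) startsWith(tolower(gene_names), p)),
                    accumulate = FALSE)
  keep <- detected >= min_cells & !is_mito
  if (!any(keep)) stop("all genes removed by preprocessing filters")
  X <- counts[, keep, drop = FALSE]
  kept_genes <- gene_names[keep]
  libs <- rowSums(X)
  target <- stats::median(libs)
  sf <- ifelse(libs > 0, target / libs, 0)
  X <- log1p(X * sf)
  colnames(X) <- kept_genes
  params <- structure(list(kept_genes = kept_genes,
                           size_factor_target = target,
                           mito_prefixes = mito_prefixes,
                           min_cells_per_gene = as.integer(min_cells),
                           log_base = "natural"),
                      class = "preprocess_params")
  list(X = X, params = params)
}

#' Replay a stored preprocessing transform on new counts
#'
#' Scales each object's counts so its total (over the supplied genes)
#' matches the reference's stored median library size, then applies
#' `log1p`.  No gene filtering is re-done: the caller subsets to the genes
#' it needs afterwards.
#'
#' @param params a `preprocess_params` from [preprocess_counts()].
#' @param counts non-negative objects x genes count matrix.
#' @return normalized log matrix of the same shape.
#' @export
apply_preprocess <- function(params, counts) {
  stopifnot(inherits(params, "preprocess_params"))
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libs <- rowSums(counts)
  sf <- ifelse(libs > 0, params$size_factor_target / libs, 0)
  log1p(counts * sf)
}

# Per-axis min-max scaling of coordinates to [0, 1] (and back).
coord_scaler <- function(Y) {
  Y <- as.matrix(Y)
  list(min = apply(Y, 2L, min), max = apply(Y, 2L, max))
}
scale_coords <- function(Y, sc) {
  Y <- as.matrix(Y)
  rng <- pmax(sc$max - sc$min, .Machine$double.eps)
  sweep(sweep(Y, 2L, sc$min, "-"), 2L, rng, "/")
}
unscale_coords <- function(Ys, sc) {
  Ys <- as.matrix(Ys)
  rng <- pmax(sc$max - sc$min, .Machine$double.eps)
  sweep(sweep(Ys, 2L, rng, "*"), 2L, sc$min, "+")
}

#' Pipeline configuration
#'
#' Settings for [two_stage_fit()].  Stage-2 hidden dims default to the
#' stage-1 hidden dims (the Winnow layer itself is dropped).
#'
#' @param task `"coordinates"`, `"ordinal"`, or `"categorical"`.
#' @param p1 Winnow-layer width: 1 gives a globally ranked selection,
#'   `> 1` per-node top-`t` unions.
#' @param hidden1,hidden2 hidden dims after the Winnow layer (stage 1) and
#'   for the stage-2 model.  The stage-1 default is empty: when `p1`
#'   equals the task's output dimension the Winnow layer then doubles as
#'   the head (a shallow additive selector, which trains reliably at desk
#'   scale because every gene edge receives direct gradient).
#' @param g number of genes kept (single-node mode); clipped with a
#'   warning if it exceeds the surviving gene count.
#' @param t per-node gene count (multi-node mode).
#' @param n_classes number of classes (ordinal / categorical).
#' @param keep_genes genes exempt from removal: always appended to the
#'   selection if absent (protects markers of small layers).
#' @param G,kappa,epsilon spline grid hyperparameters.
#' @param use_relu use the ReLU-augmented edge activation.
#' @param epochs,batch_size,learning_rate,grid_update_epochs training
#'   settings (see [train_config()]).
#' @param weight_decay1,weight_decay2 decoupled weight decay per stage.
#'   Stage 1 uses strong decay: it starves the spline weights of
#'   uninformative genes, which is the winnowing pressure the selector
#'   reads off `w_s`.  Stage 2 uses a conventional mild decay, since its
#'   job is prediction, not selection.
#' @param seed master seed; all stage seeds derive from it.
#' @param weight_classes compute inverse-frequency class weights for the
#'   loss (classification tasks).
#' @param mito_prefixes,min_cells preprocessing settings.
#' @param verbose log stage boundaries with parameter echoes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = c("ordinal", "coordinates", "categorical"),
                            p1 = 1L, hidden1 = integer(0), hidden2 = 8L,
                            g = 20L, t = NULL, n_classes = NULL,
                            keep_genes = NULL,
                            G = 5L, kappa = 3L, epsilon = 0.02,
                            use_relu = TRUE,
                            epochs = 40L, batch_size = 128L,
                            learning_rate = 5e-3,
                            grid_update_epochs = c(1L, 10L, 25L, 50L),
                            weight_decay1 = 2, weight_decay2 = 1e-2,
                            seed = 1L, weight_classes = TRUE,
                            mito_prefixes = c("MT-", "mt-"), min_cells = 3L,
                            verbose = FALSE) {
  task <- match.arg(task)
  if (is.null(hidden2)) hidden2 <- hidden1
  structure(list(task = task, p1 = as.integer(p1),
                 hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 g = as.integer(g), t = if (is.null(t)) NULL else as.integer(t),
                 n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
                 keep_genes = keep_genes,
                 G = as.integer(G), kappa = as.integer(kappa), epsilon = epsilon,
                 use_relu = isTRUE(use_relu),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 grid_update_epochs = as.integer(grid_update_epochs),
                 weight_decay1 = weight_decay1, weight_decay2 = weight_decay2,
                 seed = as.integer(seed), weight_classes = isTRUE(weight_classes),
                 mito_prefixes = mito_prefixes, min_cells = as.integer(min_cells),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage_log <- function(cfg, ...) if (cfg$verbose) message(sprintf(...))

train_cfg_from <- function(cfg, seed, weight_decay) {
  train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
               learning_rate = cfg$learning_rate, seed = seed,
               grid_update_epochs = cfg$grid_update_epochs,
               weight_decay = weight_decay,
               verbose = cfg$verbose)
}

prepare_task_target <- function(cfg, Y) {
  if (cfg$task == "coordinates") {
    sc <- coord_scaler(Y)
    list(Y = scale_coords(Y, sc), scaler = sc, class_weights = NULL)
  } else {
    labels <- as.integer(Y)
    ncl <- cfg$n_classes %||% (max(labels) + 1L)
    cw <- if (cfg$weight_classes) compute_class_weights(labels, ncl) else NULL
    list(Y = labels, scaler = NULL, class_weights = cw, n_classes = ncl)
  }
}

#' Fit the stage-1 (Winnow) model
#'
#' Trains a KAN with dims `[m, p1, hidden..., out]` whose first layer
#' feeds gene selection.
#'
#' @param X preprocessed matrix.
#' @param Y targets (scaled coordinates or 0-based labels).
#' @param p1 Winnow width.
#' @param hidden hidden dims after the Winnow layer.
#' @param task,n_classes task spec.
#' @param cfg a [train_config()].
#' @param G,kappa,epsilon,use_relu model hyperparameters.
#' @return list from [train_kan()]: trained `model` plus loss `history`.
#' @export
fit_stage1 <- function(X, Y, p1, hidden, task, cfg, n_classes = NULL,
                       G = 5L, kappa = 3L, epsilon = 0.02, use_relu = TRUE) {
  if (p1 < 1L) stop("p1 must be >= 1")
  out <- out_dim_for_task(task, n_classes)
  # shallow additive selector: with no hidden dims and a Winnow width
  # matching the head, the Winnow layer IS the output layer
  dims <- if (length(hidden) == 0L && p1 == out) c(ncol(X), out)
          else c(ncol(X), p1, hidden, out)
  model <- init_model(dims, task = task, n_classes = n_classes, G = G,
                      kappa = kappa, epsilon = epsilon, use_relu = use_relu,
                      seed = cfg$seed)
  train_kan(model, X, Y, cfg)
}

#' Fit the stage-2 model on the reduced gene set
#'
#' A fresh model (no weight reuse from stage 1) with dims
#' `[g, hidden..., out]` trained from scratch on the reduced matrix.
#'
#' @inheritParams fit_stage1
#' @param X_reduced the `n x g` reduced matrix.
#' @export
fit_stage2 <- function(X_reduced, Y, hidden, task, cfg, n_classes = NULL,
                       G = 5L, kappa = 3L, epsilon = 0.02, use_relu = TRUE) {
  if (ncol(X_reduced) < 1L) stop("need at least one gene")
  dims <- c(ncol(X_reduced), hidden, out_dim_for_task(task, n_classes))
  model <- init_model(dims, task = task, n_classes = n_classes, G = G,
                      kappa = kappa, epsilon = epsilon, use_relu = use_relu,
                      seed = cfg$seed)
  train_kan(model, X_reduced, Y, cfg)
}

#' Two-stage Winnow fit
#'
#' The full scheme: preprocess, train the stage-1 Winnow model, read gene
#' importances off its first layer, reduce the matrix to the selected
#' genes, and train the stage-2 model from scratch on the reduction.  For
#' the coordinates task the targets are min-max scaled to `[0, 1]` per
#' axis before training and the scaler stored for inverse transformation
#' at prediction time.
#'
#' @param counts raw objects x genes count matrix (gene names as column
#'   names).
#' @param Y targets: `n x 2` coordinates or 0-based integer labels.
#' @param config a [pipeline_config()].
#' @return an object of class `kan_fit` carrying the preprocessing
#'   parameters, both models, the selection, and the coordinate scaler.
#' @export
two_stage_fit <- function(counts, Y, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  stage_log(config, "[preprocess] %d objects x %d genes, min_cells = %d",
            nrow(counts), ncol(counts), config$min_cells)
  pp <- preprocess_counts(counts, mito_prefixes = config$mito_prefixes,
                          min_cells = config$min_cells)
  X <- pp$X
  tt <- prepare_task_target(config, Y)
  ncl <- tt$n_classes

  cfg1 <- train_cfg_from(config, seeds[1L], config$weight_decay1)
  cfg1$class_weights <- tt$class_weights
  stage_log(config, "[stage 1] dims [%s], task %s, %d epochs",
            paste(c(ncol(X), config$p1, config$hidden1), collapse = ", "),
            config$task, cfg1$epochs)
  s1 <- fit_stage1(X, tt$Y, config$p1, config$hidden1, config$task, cfg1,
                   n_classes = ncl, G = config$G, kappa = config$kappa,
                   epsilon = config$epsilon, use_relu = config$use_relu)

  layer1 <- s1$model$layers[[1L]]
  if (config$p1 == 1L) {
    g <- config$g
    if (g > ncol(X)) {
      warning(sprintf("g = %d exceeds the %d surviving genes; clipped", g, ncol(X)))
      g <- ncol(X)
    }
    sel <- rank_genes_single_node(layer1, g, gene_names = colnames(X))
  } else {
    if (is.null(config$t)) stop("multi-node Winnow layer (p1 > 1) requires t")
    t <- min(config$t, ncol(X))
    sel <- select_genes_multi_node(layer1, t, gene_names = colnames(X))
  }
  if (!is.null(config$keep_genes)) {
    extra <- setdiff(intersect(config$keep_genes, colnames(X)), sel$genes)
    if (length(extra)) {
      sel <- new_selection_result(c(sel$genes, extra),
                                  if (length(sel$scores)) c(sel$scores, rep(NA_real_, length(extra))) else numeric(0),
                                  sel$mode, sel$t_per_node)
    }
  }
  stage_log(config, "[select] %d gene(s), mode %s", sel$g_total, sel$mode)

  Xr <- reduce_matrix(X, sel)
  cfg2 <- train_cfg_from(config, seeds[2L], config$weight_decay2)
  cfg2$class_weights <- tt$class_weights
  stage_log(config, "[stage 2] dims [%s]",
            paste(c(ncol(Xr), config$hidden2), collapse = ", "))
  s2 <- fit_stage2(Xr, tt$Y, config$hidden2, config$task, cfg2,
                   n_classes = ncl, G = config$G, kappa = config$kappa,
                   epsilon = config$epsilon, use_relu = config$use_relu)

  structure(list(preprocess = pp$params,
                 stage1_model = s1$model, stage1_history = s1$history,
                 selection = sel,
                 stage2_model = s2$model, stage2_history = s2$history,
                 coord_scaler = tt$scaler, task = config$task,
                 n_classes = ncl, config = config),
            class = "kan_fit")
}

#' Predict spatial information for a query expression matrix
#'
#' Replays the stored library-size + `log1p` transform, aligns the query
#' columns to the selected genes by name, and forwards through the stage-2
#' model.  Coordinates are inverse-scaled to the training units; ordinal
#' outputs are decoded by [coral_decode()] (cumulative probabilities also
#' returned); categorical outputs return per-class probabilities and the
#' argmax label.
#'
#' @param fit a [two_stage_fit()] result.
#' @param counts query count matrix whose column names include every
#'   selected gene.
#' @return list of class `kan_prediction`; fields depend on the task.
#' @export
predict_query <- function(fit, counts) {
  stopifnot(inherits(fit, "kan_fit"))
  counts <- as.matrix(counts)
  nms <- colnames(counts)
  if (is.null(nms)) stop("query matrix must carry gene names as column names")
  missing <- setdiff(fit$selection$genes, nms)
  if (length(missing)) {
    stop("query is missing selected gene(s): ", paste(missing, collapse = ", "))
  }
  Xq <- apply_preprocess(fit$preprocess, counts)
  Xq <- Xq[, match(fit$selection$genes, nms), drop = FALSE]
  out <- kan_forward(Xq, fit$stage2_model)
  if (fit$task == "coordinates") {
    pred <- unscale_coords(out, fit$coord_scaler)
    colnames(pred) <- c("x", "y")
    structure(list(task = fit$task, coords = pred), class = "kan_prediction")
  } else if (fit$task == "ordinal") {
    structure(list(task = fit$task, labels = coral_decode(out),
                   cum_probs = stats::plogis(out)),
              class = "kan_prediction")
  } else {
    P <- exp(log_softmax(out))
    structure(list(task = fit$task, labels = as.integer(max.col(P) - 1L),
                   probs = P),
              class = "kan_prediction")
  }
}
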