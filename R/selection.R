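# The Winnow selector: gene importances read off the first KAN layer's
# spline weights w_s, and the reduced training matrix for the stage-2
# refit.  Importance uses |w_s|: a large negative spline weight is as
# influential as a large positive one.

new_selection_result <- function(genes, scores, mode, t_per_node = NA_integer_) {
  structure(list(genes = as.character(genes), scores = scores, mode = mode,
                 t_per_node = t_per_node, g_total = length(genes)),
            class = "selection_result")
}

default_gene_names <- function(m) sprintf("gene%d", seq_len(m))

#' Rank genes by a single-node Winnow layer
#'
#' For a first layer with one output node every gene has exactly one edge;
#' genes are ranked by the absolute spline weight `|w_s|` of that edge,
#' decreasing, ties broken by ascending gene index, and the top `g` are
#' returned with their scores.
#'
#' @param layer1 the first layer of a trained `kan_model` (out_dim 1).
#' @param g number of genes to keep, `g <= in_dim`.
#' @param gene_names optional character vector naming the input genes.
#' @return a `selection_result` with `mode = "single_node_ranked"`.
#' @export
rank_genes_single_node <- function(layer1, g, gene_names = NULL) {
  if (layer1$out_dim != 1L) {
    stop("layer has out_dim > 1: use select_genes_multi_node() for multi-node Winnow layers")
  }
  g <- as.integer(g)
  if (g < 1L || g > layer1$in_dim) stop("g must lie in 1 .. in_dim")
  if (is.null(gene_names)) gene_names <- default_gene_names(layer1$in_dim)
  imp <- abs(layer1$Ws[1L, ])
  ord <- order(-imp, seq_along(imp))   # ties: lower gene index first
  top <- ord[seq_len(g)]
  new_selection_result(gene_names[top], imp[top], "single_node_ranked")
}

#' Per-node top genes of a multi-node Winnow layer (union)
#'
#' For each of the `p_1 > 1` first-layer nodes, the `t` genes with the
#' largest `|w_s|` on edges into that node form the node's top set; the
#' result is their union.  Spline weights of different nodes are not
#' comparable, so no global ranking (and no scores) are emitted; genes are
#' returned in ascending input-index order.
#'
#' @param layer1 the first layer of a trained `kan_model` (out_dim > 1).
#' @param t number of genes taken per node.
#' @param gene_names optional character vector naming the input genes.
#' @return a `selection_result` with `mode = "multi_node_union"`.
#' @export
select_genes_multi_node <- function(layer1, t, gene_names = NULL) {
  if (layer1$out_dim == 1L) {
    stop("layer has out_dim 1: use rank_genes_single_node()")
  }
  t <- as.integer(t)
  if (t < 1L || t > layer1$in_dim) stop("t must lie in 1 .. in_dim")
  if (is.null(gene_names)) gene_names <- default_gene_names(layer1$in_dim)
  sel <- logical(layer1$in_dim)
  for (o in seq_len(layer1$out_dim)) {
    imp <- abs(layer1$Ws[o, ])
    ord <- order(-imp, seq_along(imp))
    sel[ord[seq_len(t)]] <- TRUE
  }
  idx <- which(sel)
  new_selection_result(gene_names[idx], numeric(0), "multi_node_union",
                       t_per_node = t)
}

#' Reduce an expression matrix to the selected genes
#'
#' Pure column subsetting, in the selection's gene order; errors listing
#' any selected gene absent from the matrix.
#'
#' @param X objects x genes matrix with gene names as column names (or
#'   positional `gene...` defaults).
#' @param sel a `selection_result`.
#' @return the `n x g` sub-matrix.
#' @export
reduce_matrix <- function(X, sel) {
  stopifnot(inherits(sel, "selection_result"))
  X <- as.matrix(X)
  nms <- colnames(X)
  if (is.null(nms)) nms <- default_gene_names(ncol(X))
  missing <- setdiff(sel$genes, nms)
  if (length(missing)) {
    stop("selected gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  out <- X[, match(sel$genes, nms), drop = FALSE]
  colnames(out) <- sel$genes
  out
}

#' Variance-ranking gene selection baseline
#'
#' Plumbing comparator standing in for highly-variable-gene selection:
#' genes ranked by per-gene variance of the (log-transformed) matrix, top
#' `g` kept.
#'
#' @param X objects x genes matrix (log scale).
#' @param g number of genes to keep.
#' @return a `selection_result` with variances as scores.
#' @export
variance_rank_baseline <- function(X, g) {
  X <- as.matrix(X)
  g <- as.integer(g)
  if (g < 1L || g > ncol(X)) stop("g must lie in 1 .. ncol(X)")
  nms <- colnames(X)
  if (is.null(nms)) nms <- default_gene_names(ncol(X))
  v <- apply(X, 2L, stats::var)
  ord <- order(-v, seq_along(v))
  top <- ord[seq_len(g)]
  new_selection_result(nms[top], v[top], "single_node_ranked")
}

#' Write / read a selected gene list
#'
#' Two-column tab-delimited text: gene name and score (NA for union-mode
#' selections).  Readable back for stage 2 and for query prediction.
#'
#' @param sel a `selection_result`.
#' @param path file path.
#' @return `write_gene_list` returns `path` invisibly; `read_gene_list`
#'   returns a `selection_result`.
#' @export
write_gene_list <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  sc <- if (length(sel$scores)) sel$scores else rep(NA_real_, length(sel$genes))
  df <- data.frame(gene = sel$genes, score = sc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(df))) {
    stop("gene list must have columns 'gene' and 'score'")
  }
  if (all(is.na(df$score))) {
    new_selection_result(df$gene, numeric(0), "multi_node_union")
  } else {
    new_selection_result(df$gene, df$score, "single_node_ranked")
  }
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection of %d gene(s), mode = %s\n", x$g_total, x$mode))
  show <- utils::head(x$genes, 10L)
  cat(" ", paste(show, collapse = ", "),
      if (x$g_total > 10L) "..." else "", "\n")
  invisible(x)
}
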