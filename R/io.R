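# Readers/writers for expression and annotation formats, and model
# persistence.  Matrices are stored as raw counts; preprocessing is always
# explicit, never implicit on read.

wk_stop_input <- function(...) {
  stop(structure(class = c("wk_input_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1L))))
}

read_id_table <- function(path, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) wk_stop_input("%s file %s needs an id column plus data", what, path)
  df
}

#' Read an expression dataset
#'
#' Two dialects.  `mtx_dir`: a directory holding `matrix.mtx`
#' (MatrixMarket coordinate), `genes.tsv` (or `features.tsv`) and
#' `barcodes.tsv`; orientation is auto-detected from the header dimensions
#' against the companion file lengths, and genes-as-rows matrices are
#' transposed to objects x genes.  `delimited`: a single tab-delimited
#' table with a header row of gene names and object ids in the first
#' column.  Optional companion files `coords.tsv` (id, x, y) and
#' `labels.tsv` (id, label) are joined by object id.
#'
#' @param path directory (`mtx_dir`) or file (`delimited`).
#' @param format `"mtx_dir"` or `"delimited"`.
#' @return list of class `st_dataset`: `counts` (dense objects x genes
#'   matrix with dimnames), `genes`, `ids`, and optional `coords`,
#'   `labels`.
#' @export
read_dataset <- function(path, format = c("mtx_dir", "delimited")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) wk_stop_input("dataset directory not found: %s", path)
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) wk_stop_input("matrix.mtx not found in %s", path)
    gf <- file.path(path, "genes.tsv")
    if (!file.exists(gf)) gf <- file.path(path, "features.tsv")
    bf <- file.path(path, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf)) {
      wk_stop_input("genes.tsv/features.tsv and barcodes.tsv required in %s", path)
    }
    M <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    ids <- utils::read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(M) == length(genes) && ncol(M) == length(ids)) {
      M <- t(M)                      # genes-as-rows dialect
    } else if (!(nrow(M) == length(ids) && ncol(M) == length(genes))) {
      wk_stop_input("matrix is %d x %d but %d barcodes and %d genes were supplied",
                    nrow(M), ncol(M), length(ids), length(genes))
    }
    dimnames(M) <- list(ids, genes)
    coords <- labels <- NULL
    cf <- file.path(path, "coords.tsv")
    if (file.exists(cf)) {
      df <- read_id_table(cf, "coords")
      i <- match(ids, df[[1L]])
      if (anyNA(i)) wk_stop_input("coords.tsv missing object id(s)")
      coords <- as.matrix(df[i, 2:3])
      rownames(coords) <- ids
    }
    lf <- file.path(path, "labels.tsv")
    if (file.exists(lf)) {
      df <- read_id_table(lf, "labels")
      i <- match(ids, df[[1L]])
      if (anyNA(i)) wk_stop_input("labels.tsv missing object id(s)")
      labels <- df[i, 2L]
    }
  } else {
    if (!file.exists(path)) wk_stop_input("dataset file not found: %s", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    genes <- colnames(M)
    rownames(M) <- ids
    coords <- labels <- NULL
  }
  if (anyDuplicated(genes)) wk_stop_input("duplicate gene names in dataset")
  structure(list(counts = M, genes = genes, ids = rownames(M),
                 coords = coords, labels = labels),
            class = "st_dataset")
}

#' Write a dataset as an MTX directory
#'
#' Writes `matrix.mtx` in the conventional genes-as-rows orientation plus
#' `genes.tsv`, `barcodes.tsv`, and (when present) `coords.tsv` /
#' `labels.tsv` keyed by object id.  Round-trips through [read_dataset()].
#'
#' @param data a list with `counts` (objects x genes, dimnames set) and
#'   optional `coords` / `labels` (e.g. a simulator output or
#'   `st_dataset`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (is.null(data$counts)) wk_stop_input("data must carry a counts matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- as.matrix(data$counts)
  ids <- rownames(M) %||% sprintf("obj%05d", seq_len(nrow(M)))
  genes <- colnames(M) %||% default_gene_names(ncol(M))
  Matrix::writeMM(methods::as(Matrix::Matrix(t(M), sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(data$coords)) {
    utils::write.table(data.frame(id = ids, x = data$coords[, 1L],
                                  y = data$coords[, 2L]),
                       file.path(dir, "coords.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(data$labels)) {
    utils::write.table(data.frame(id = ids, label = data$labels),
                       file.path(dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

FIT_ARCHIVE_VERSION <- 1L

#' Save / load a fitted two-stage model
#'
#' Single-file archive holding the complete [two_stage_fit()] result:
#' preprocessing parameters, both models with all grids and weights, the
#' selection, and the coordinate scaler.  The round trip is bit-exact, so
#' predictions before and after reload are identical.
#'
#' @param fit a `kan_fit`.
#' @param path archive file path.
#' @return `save_fit` returns `path` invisibly; `load_fit` the restored
#'   `kan_fit`.
#' @export
save_fit <- function(fit, path) {
  stopifnot(inherits(fit, "kan_fit"))
  saveRDS(list(format = "winnowkan_fit", version = FIT_ARCHIVE_VERSION,
               fit = fit), path)
  invisible(path)
}

#' @rdname save_fit
#' @export
load_fit <- function(path) {
  if (!file.exists(path)) wk_stop_input("fit archive not found: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) wk_stop_input("corrupted fit archive %s: %s",
                                                    path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "winnowkan_fit")) {
    wk_stop_input("%s is not a winnowkan fit archive", path)
  }
  if (!identical(obj$version, FIT_ARCHIVE_VERSION)) {
    wk_stop_input("fit archive version %s not supported by this build (expects %d)",
                  as.character(obj$version), FIT_ARCHIVE_VERSION)
  }
  obj$fit
}
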