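#' Expression matrix with a layer tag
#'
#' Lightweight container for a gene x cell expression matrix. The `layer`
#' records what the values are (`counts`, `TPM`, `logTPM`, `FPM`,
#' `correctedFPM`, ...) and is checked by every consumer so that, e.g., the
#' cell filter cannot silently run on raw counts. Per-cell metadata
#' (source population, optional cluster label) travel with the matrix.
#'
#' @param values numeric matrix, genes in rows, cells in columns, with
#'   dimnames. All values must be finite and non-negative.
#' @param layer character scalar naming the layer.
#' @param source optional character vector (length = n cells) with values
#'   `"cell"` or `"nucleus"`.
#' @param cluster optional character/factor vector of per-cell cluster labels.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer, source = NULL, cluster = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("`values` must have gene (row) names")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("`values` must have cell (column) names")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids in `values`")
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  if (any(values < 0))
    stop("`values` contains negative entries")
  if (!is.character(layer) || length(layer) != 1L)
    stop("`layer` must be a single string")
  nc <- ncol(values)
  if (!is.null(source)) {
    source <- as.character(source)
    if (length(source) != nc) stop("`source` length must equal ncol(values)")
    if (!all(source %in% c("cell", "nucleus")))
      stop("`source` values must be 'cell' or 'nucleus'")
  }
  if (!is.null(cluster)) {
    cluster <- as.character(cluster)
    if (length(cluster) != nc) stop("`cluster` length must equal ncol(values)")
  }
  structure(
    list(values = values, layer = layer, source = source, cluster = cluster),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (!is.null(x$source))
    print(table(source = x$source))
  invisible(x)
}

#' Gene and cell identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of ids.
#' @export
em_genes <- function(x) rownames(x$values)

#' @rdname em_genes
#' @export
em_cells <- function(x) colnames(x$values)

#' Layer tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return character scalar.
#' @export
em_layer <- function(x) x$layer

#' Numeric values of an expression matrix
#' @param x an `expr_matrix`.
#' @return the underlying numeric matrix.
#' @export
em_values <- function(x) x$values

#' Subset an expression matrix
#'
#' Row (gene) and column (cell) subsetting; per-cell metadata are subset in
#' step with the columns and the layer tag is preserved.
#' @param x an `expr_matrix`.
#' @param i gene index/names.
#' @param j cell index/names.
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  jj <- seq_len(ncol(x$values))
  names(jj) <- colnames(x$values)
  jidx <- jj[j]
  expr_matrix(v, x$layer,
              source = if (!is.null(x$source)) x$source[jidx],
              cluster = if (!is.null(x$cluster)) x$cluster[jidx])
}

.check_layer <- function(x, expected, what = "input") {
  if (!inherits(x, "expr_matrix"))
    stop(sprintf("%s must be an expr_matrix", what))
  if (!em_layer(x) %in% expected)
    stop(sprintf("%s has layer '%s'; expected %s", what, em_layer(x),
                 paste(sQuote(expected), collapse = " or ")))
  invisible(TRUE)
}

#' log2(x + 1) transform of an expression matrix
#'
#' Applies `log2(value + 1)` entry-wise and prefixes the layer with `log`
#' (e.g. `TPM` becomes `logTPM`). Log base 2 is used throughout the package;
#' thresholds quoted as "log(expr + 1) >= 1" are interpreted on this scale.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` with transformed values.
#' @export
log1p_expr <- function(x) {
  if (!inherits(x, "expr_matrix")) stop("`x` must be an expr_matrix")
  if (startsWith(em_layer(x), "log"))
    stop("matrix is already log-transformed (layer '", em_layer(x), "')")
  out <- x
  out$values <- log2(x$values + 1)
  out$layer <- paste0("log", em_layer(x))
  out
}

#' Read / write an expression matrix as TSV
#'
#' Plain-text round trip: genes in rows, cells in columns, first column
#' `gene_id`. Cell metadata, when present, are written to a sidecar file
#' `<path>.cells.tsv` with columns `cell_id`, `source`, `cluster`.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @param layer layer tag to assign on read.
#' @return `read_expr_matrix` returns an `expr_matrix`;
#'   `write_expr_matrix` returns `path` invisibly.
#' @export
write_expr_matrix <- function(x, path) {
  df <- data.frame(gene_id = em_genes(x), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$source) || !is.null(x$cluster)) {
    meta <- data.frame(
      cell_id = em_cells(x),
      source = if (is.null(x$source)) NA_character_ else x$source,
      cluster = if (is.null(x$cluster)) NA_character_ else x$cluster
    )
    utils::write.table(meta, paste0(path, ".cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path, layer) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  src <- clus <- NULL
  meta_path <- paste0(path, ".cells.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    meta <- meta[match(colnames(v), meta$cell_id), ]
    if (!all(is.na(meta$source))) src <- meta$source
    if (!all(is.na(meta$cluster))) clus <- meta$cluster
  }
  expr_matrix(v, layer, source = src, cluster = clus)
}
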