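#' Convert counts to transcripts per million (TPM)
#'
#' Per cell, counts are divided by gene length to give per-base rates, and
#' rates are rescaled to sum to one million. The default length is the
#' genic (intron-inclusive) length, matching intron-inclusive whole-gene
#' counting; `length_mode = "exonic"` uses the exon-union length instead.
#' All-zero cells stay all-zero (no NaN) and are listed in the
#' `zero_cells` attribute.
#'
#' @param x an `expr_matrix` with layer `counts`.
#' @param catalog a `gene_catalog` covering every gene in `x`.
#' @param length_mode `"genic"` (default) or `"exonic"`.
#' @return an `expr_matrix` with layer `TPM`.
#' @export
counts_to_tpm <- function(x, catalog, length_mode = c("genic", "exonic")) {
  .check_layer(x, "counts")
  length_mode <- match.arg(length_mode)
  cat_rows <- .catalog_lookup(catalog, em_genes(x))
  len <- if (length_mode == "genic") cat_rows$genic_length else cat_rows$exonic_length
  if (any(len < 1)) stop("gene length < 1 in catalog")
  rate <- x$values / len
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- 1  # keep all-zero columns all-zero
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- expr_matrix(tpm, "TPM", source = x$source, cluster = x$cluster)
  attr(out, "zero_cells") <- em_cells(x)[zero]
  attr(out, "length_mode") <- length_mode
  out
}

#' Convert counts to fragments per million (FPM)
#'
#' Library-size scaling without length normalisation: each cell's counts
#' are rescaled to sum to one million. This is the quantification on which
#' per-gene M values and the bias model operate.
#'
#' @param x an `expr_matrix` with layer `counts`.
#' @return an `expr_matrix` with layer `FPM`.
#' @export
counts_to_fpm <- function(x) {
  .check_layer(x, "counts")
  tot <- colSums(x$values)
  zero <- tot == 0
  tot[zero] <- 1
  fpm <- sweep(x$values, 2, tot, "/") * 1e6
  out <- expr_matrix(fpm, "FPM", source = x$source, cluster = x$cluster)
  attr(out, "zero_cells") <- em_cells(x)[zero]
  out
}

#' ERCC-only TPM
#'
#' Computes TPM restricted to spike-in rows (identified by id prefix),
#' independent of any endogenous genes present in the matrix. Without a
#' catalog all spikes get unit length, i.e. pure library-size
#' normalisation over spikes; with a catalog providing spike lengths the
#' computation matches [counts_to_tpm()] on the spike block.
#'
#' @param x an `expr_matrix` with layer `counts`; may contain a mix of
#'   spikes and endogenous genes.
#' @param catalog optional `gene_catalog` with spike lengths.
#' @param prefix spike id prefix, default `"ERCC-"`.
#' @return an `expr_matrix` (spikes only) with layer `TPM`.
#' @export
ercc_tpm <- function(x, catalog = NULL, prefix = "ERCC-") {
  .check_layer(x, "counts")
  keep <- startsWith(em_genes(x), prefix)
  if (!any(keep)) stop("no spike rows with prefix '", prefix, "'")
  spikes <- x[keep, ]
  if (is.null(catalog)) {
    tot <- colSums(spikes$values)
    zero <- tot == 0
    tot[zero] <- 1
    tpm <- sweep(spikes$values, 2, tot, "/") * 1e6
    out <- expr_matrix(tpm, "TPM", source = spikes$source,
                       cluster = spikes$cluster)
    attr(out, "zero_cells") <- em_cells(spikes)[zero]
    out
  } else {
    counts_to_tpm(spikes, catalog)
  }
}

#' Per-cell correlation of spike-in expression with input quantity
#'
#' Pearson correlation, per cell, between spike expression and the known
#' spike input quantities over the spikes shared between matrix and
#' reference. On the log scale the comparison is log2(TPM + 1) versus
#' log10(input). Cells whose observed spike vector has zero variance get
#' `NA` with a reason code instead of an error.
#'
#' @param x spike `expr_matrix` (typically TPM from [ercc_tpm()]).
#' @param reference data frame with columns `spike_id`, `input_quantity`
#'   (strictly positive).
#' @param scale `"log"` (default) or `"linear"`.
#' @return data frame with columns `cell_id`, `r`, `n_spikes`, `reason`
#'   (`NA` when r is defined).
#' @export
ercc_correlation <- function(x, reference, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!inherits(x, "expr_matrix")) stop("`x` must be an expr_matrix")
  stopifnot(all(c("spike_id", "input_quantity") %in% names(reference)))
  if (any(reference$input_quantity <= 0))
    stop("spike input quantities must be strictly positive")
  if (anyDuplicated(reference$spike_id)) stop("duplicated spike ids")
  shared <- intersect(em_genes(x), reference$spike_id)
  if (length(shared) < 3)
    stop("fewer than 3 spikes shared between matrix and reference")
  obs <- x$values[shared, , drop = FALSE]
  q <- reference$input_quantity[match(shared, reference$spike_id)]
  if (scale == "log") {
    obs <- log2(obs + 1)
    q <- log10(q)
  }
  r <- rep(NA_real_, ncol(obs))
  reason <- rep(NA_character_, ncol(obs))
  for (j in seq_len(ncol(obs))) {
    if (stats::sd(obs[, j]) == 0) {
      reason[j] <- "zero variance in observed spikes"
    } else {
      r[j] <- stats::cor(obs[, j], q)
    }
  }
  data.frame(cell_id = em_cells(x), r = r,
             n_spikes = length(shared), reason = reason,
             stringsAsFactors = FALSE)
}

#' Filter cells by number of expressed genes
#'
#' A cell is kept iff at least `min_genes` genes have
#' `log2(TPM + 1) >= expr_threshold`. Defaults (1000 genes at threshold 1)
#' are the standard inclusion rule for these data; both are configurable.
#'
#' @param x an `expr_matrix` with layer `TPM`.
#' @param min_genes minimum number of qualifying genes, default 1000.
#' @param expr_threshold expression threshold on log2(TPM + 1), default 1.
#' @return list with `matrix` (kept cells) and `report` (per-cell
#'   `cell_id`, `n_expressed`, `kept`); thresholds and log base are
#'   recorded as attributes of the report.
#' @export
filter_cells <- function(x, min_genes = 1000, expr_threshold = 1) {
  .check_layer(x, "TPM")
  n_expressed <- colSums(log2(x$values + 1) >= expr_threshold)
  kept <- n_expressed >= min_genes
  report <- data.frame(cell_id = em_cells(x),
                       n_expressed = as.integer(n_expressed),
                       kept = kept, stringsAsFactors = FALSE)
  attr(report, "min_genes") <- min_genes
  attr(report, "expr_threshold") <- expr_threshold
  attr(report, "log_base") <- 2
  list(matrix = x[, kept], report = report)
}

#' Filter genes by number of cells expressing them
#'
#' A gene is kept iff it is expressed (`log2(TPM + 1) >= expr_threshold`)
#' in at least `min_cells` cells. The expression definition deliberately
#' reuses the cell-filter definition.
#'
#' @param x an `expr_matrix` with layer `TPM`.
#' @param min_cells minimum number of expressing cells, default 3.
#' @param expr_threshold threshold on log2(TPM + 1), default 1.
#' @return list with `matrix` (kept genes) and `report` (per-gene
#'   `gene_id`, `n_cells_expressed`, `kept`).
#' @export
filter_genes <- function(x, min_cells = 3, expr_threshold = 1) {
  .check_layer(x, "TPM")
  n_cells <- rowSums(log2(x$values + 1) >= expr_threshold)
  kept <- n_cells >= min_cells
  report <- data.frame(gene_id = em_genes(x),
                       n_cells_expressed = as.integer(n_cells),
                       kept = kept, stringsAsFactors = FALSE)
  attr(report, "min_cells") <- min_cells
  attr(report, "expr_threshold") <- expr_threshold
  list(matrix = x[kept, ], report = report)
}

#' Per-cell read-category proportions
#'
#' Converts a cells x categories count table (e.g. CDS exon / intron /
#' 3'UTR / 5'UTR) into per-cell proportions summing to 1. Cells with zero
#' total reads get `NA` proportions and are flagged.
#'
#' @param category_counts numeric matrix or data frame, cells in rows,
#'   categories in columns, non-negative.
#' @return data frame of proportions with a logical `flagged_zero` column.
#' @export
region_proportions <- function(category_counts) {
  m <- as.matrix(category_counts)
  if (any(m < 0)) stop("negative category counts")
  tot <- rowSums(m)
  zero <- tot == 0
  p <- m / ifelse(tot == 0, 1, tot)
  p[zero, ] <- NA_real_
  out <- as.data.frame(p)
  out$flagged_zero <- zero
  out
}
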