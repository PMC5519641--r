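.row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Differential detection between matched cells and nuclei
#'
#' Per-gene two-group comparison on log-transformed expression
#' (log2(expr + 1) layers). The log fold change is the difference of group
#' means (cells minus nuclei). Genes are screened on the fold change
#' first: only genes with `|lfc| > lfc_threshold` are tested (a Welch
#' unequal-variance t test); screened-out genes carry `NA` p values. A
#' gene passes when it survives the screen and `p < p_threshold`.
#'
#' @param cell_matrix log-layer `expr_matrix` for whole cells (>= 2 cells).
#' @param nuc_matrix log-layer `expr_matrix` for nuclei (>= 2 cells).
#' @param lfc_threshold fold-change screen, default 1.0 (log2 units).
#' @param p_threshold significance threshold, default 0.01.
#' @return data frame of class `diff_detection` with columns `gene_id`,
#'   `log_fold_change`, `p_value`, `direction`
#'   (`up_in_cells`/`up_in_nuclei`), `passes`.
#' @export
differential_detection <- function(cell_matrix, nuc_matrix,
                                   lfc_threshold = 1.0, p_threshold = 0.01) {
  for (m in list(cell_matrix, nuc_matrix))
    if (!inherits(m, "expr_matrix") || !startsWith(em_layer(m), "log"))
      stop("differential detection requires log-transformed expr_matrix inputs")
  if (ncol(cell_matrix$values) < 2L || ncol(nuc_matrix$values) < 2L)
    stop("each group needs at least 2 cells")
  shared <- intersect(em_genes(cell_matrix), em_genes(nuc_matrix))
  if (length(shared) == 0L) stop("no shared genes")
  xc <- cell_matrix$values[shared, , drop = FALSE]
  xn <- nuc_matrix$values[shared, , drop = FALSE]
  nc <- ncol(xc); nn <- ncol(xn)
  mc <- rowMeans(xc); mn <- rowMeans(xn)
  lfc <- mc - mn
  screened <- abs(lfc) > lfc_threshold
  p <- rep(NA_real_, length(shared))
  if (any(screened)) {
    vc <- .row_vars(xc[screened, , drop = FALSE])
    vn <- .row_vars(xn[screened, , drop = FALSE])
    se2 <- vc / nc + vn / nn
    tstat <- lfc[screened] / sqrt(se2)
    df <- se2^2 / ((vc / nc)^2 / (nc - 1) + (vn / nn)^2 / (nn - 1))
    pv <- 2 * stats::pt(-abs(tstat), df)
    pv[se2 == 0] <- 0   # exactly separated constant groups
    p[screened] <- pv
  }
  out <- data.frame(
    gene_id = shared,
    log_fold_change = lfc,
    p_value = p,
    direction = ifelse(lfc >= 0, "up_in_cells", "up_in_nuclei"),
    passes = screened & !is.na(p) & p < p_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("diff_detection", "data.frame")
  out
}

#' Top differentially detected genes
#'
#' Subset of results with `p_value` strictly below `p_cut`, ordered by
#' increasing p value (the gene set a stringent heatmap would display).
#'
#' @param results a `diff_detection` data frame.
#' @param p_cut strict p-value cutoff, default 1e-20.
#' @return a `diff_detection` subset ordered by p value.
#' @export
top_gene_table <- function(results, p_cut = 1e-20) {
  stopifnot(inherits(results, "diff_detection"))
  keep <- !is.na(results$p_value) & results$p_value < p_cut
  out <- results[keep, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Gene-length difference between up- and down-detected gene sets
#'
#' Tests whether genes detected higher in cells differ in genic length
#' from genes detected higher in nuclei: a two-sided equal-variance
#' Student t test and a Wilcoxon rank-sum test on log10 genic length.
#' Before correction, nuclear length bias makes the "up in nuclei" set
#' dramatically longer; after a successful correction both tests should be
#' non-significant.
#'
#' @param up_genes,down_genes disjoint character vectors of gene ids
#'   (each >= 2), e.g. split by `direction` from
#'   [differential_detection()].
#' @param catalog a `gene_catalog` containing all the genes.
#' @param stage label `"before"` or `"after"` (bookkeeping only).
#' @return a list of class `bias_test_report` with set sizes, mean/median
#'   genic lengths, `student_t_p` and `wilcoxon_p`.
#' @export
length_bias_test <- function(up_genes, down_genes, catalog,
                             stage = c("before", "after")) {
  stage <- match.arg(stage)
  if (length(intersect(up_genes, down_genes)) > 0)
    stop("up and down gene sets overlap")
  if (length(up_genes) < 2 || length(down_genes) < 2)
    stop("each gene set needs at least 2 genes")
  lu <- log10(.catalog_lookup(catalog, up_genes, "up set")$genic_length)
  ld <- log10(.catalog_lookup(catalog, down_genes, "down set")$genic_length)
  if (stats::sd(lu) == 0 && stats::sd(ld) == 0) {
    # both groups constant: no within-group variance for a t statistic;
    # equal constants mean no difference, distinct constants complete
    # separation
    tp <- if (isTRUE(all.equal(mean(lu), mean(ld)))) 1 else 0
    wp <- stats::wilcox.test(lu, ld, exact = FALSE)$p.value
  } else {
    tp <- stats::t.test(lu, ld, var.equal = TRUE)$p.value
    wp <- stats::wilcox.test(lu, ld, exact = FALSE)$p.value
  }
  structure(list(
    n_up = length(up_genes), n_down = length(down_genes),
    mean_length_up = mean(10^lu), mean_length_down = mean(10^ld),
    median_length_up = stats::median(10^lu),
    median_length_down = stats::median(10^ld),
    student_t_p = tp, wilcoxon_p = wp, stage = stage
  ), class = "bias_test_report")
}

#' @export
print.bias_test_report <- function(x, ...) {
  cat(sprintf("length-bias test (%s correction): %d up vs %d down genes\n",
              x$stage, x$n_up, x$n_down))
  cat(sprintf("  median genic length: up %.0f bp, down %.0f bp\n",
              x$median_length_up, x$median_length_down))
  cat(sprintf("  Student t p = %.3g | Wilcoxon p = %.3g\n",
              x$student_t_p, x$wilcoxon_p))
  invisible(x)
}

#' Gene-type composition of detected genes
#'
#' A gene counts as detected in a cell when its count reaches
#' `detect_min_count` (default 4). Per cell, the detected genes are broken
#' down by gene type into percentages summing to 100; totals and a
#' per-source summary (mean detected genes and mean percentage per type)
#' are returned alongside.
#'
#' @param x an `expr_matrix` with layer `counts` and per-cell `source`.
#' @param catalog a `gene_catalog`.
#' @param detect_min_count detection threshold, default 4.
#' @return list with `per_cell` (cell_id, source, n_detected, one `pct_*`
#'   column per gene type) and `by_source` (mean n_detected and mean
#'   percentages per source).
#' @export
gene_type_composition <- function(x, catalog, detect_min_count = 4) {
  .check_layer(x, "counts")
  cat_rows <- .catalog_lookup(catalog, em_genes(x))
  detected <- x$values >= detect_min_count
  types <- sort(unique(cat_rows$gene_type))
  n_det <- colSums(detected)
  by_type <- rowsum(detected + 0, group = cat_rows$gene_type)  # types x cells
  pct <- t(by_type) / ifelse(n_det == 0, 1, n_det) * 100
  colnames(pct) <- paste0("pct_", rownames(by_type))
  per_cell <- data.frame(
    cell_id = em_cells(x),
    source = if (is.null(x$source)) NA_character_ else x$source,
    n_detected = as.integer(n_det),
    pct, check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(per_cell) <- NULL
  by_source <- NULL
  if (!is.null(x$source)) {
    agg <- stats::aggregate(per_cell[, c("n_detected", colnames(pct))],
                            by = list(source = per_cell$source), FUN = mean)
    by_source <- agg
  }
  list(per_cell = per_cell, by_source = by_source,
       detect_min_count = detect_min_count)
}

#' Before/after bias-correction comparison
#'
#' Combines pre- and post-correction differential-detection results and
#' length-bias tests into one report with a machine-readable verdict:
#' `bias_removed` is true iff both post-correction length-test p values
#' strictly exceed `alpha`.
#'
#' @param pre_results,post_results `diff_detection` tables computed on the
#'   same gene universe.
#' @param pre_bias,post_bias `bias_test_report` objects for the two stages.
#' @param alpha significance level for the verdict, default 0.05.
#' @return a list of class `before_after_report` with a `comparison` data
#'   frame, the two bias reports, `alpha` and `bias_removed`.
#' @export
before_after_report <- function(pre_results, post_results,
                                pre_bias, post_bias, alpha = 0.05) {
  stopifnot(inherits(pre_results, "diff_detection"),
            inherits(post_results, "diff_detection"),
            inherits(pre_bias, "bias_test_report"),
            inherits(post_bias, "bias_test_report"))
  if (!setequal(pre_results$gene_id, post_results$gene_id))
    stop("pre and post results cover different gene universes")
  comparison <- data.frame(
    stage = c("before", "after"),
    n_pass = c(sum(pre_results$passes), sum(post_results$passes)),
    n_up_in_cells = c(sum(pre_results$passes &
                            pre_results$direction == "up_in_cells"),
                      sum(post_results$passes &
                            post_results$direction == "up_in_cells")),
    n_up_in_nuclei = c(sum(pre_results$passes &
                             pre_results$direction == "up_in_nuclei"),
                       sum(post_results$passes &
                             post_results$direction == "up_in_nuclei")),
    student_t_p = c(pre_bias$student_t_p, post_bias$student_t_p),
    wilcoxon_p = c(pre_bias$wilcoxon_p, post_bias$wilcoxon_p)
  )
  structure(list(
    comparison = comparison,
    pre_bias = pre_bias, post_bias = post_bias, alpha = alpha,
    bias_removed = (post_bias$student_t_p > alpha) &&
      (post_bias$wilcoxon_p > alpha)
  ), class = "before_after_report")
}

#' @export
print.before_after_report <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("bias_removed (both post p > %.2g): %s\n",
              x$alpha, x$bias_removed))
  invisible(x)
}
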