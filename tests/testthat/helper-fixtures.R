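# programmatic fixtures shared across test files

# minimal catalog from explicit lengths
make_catalog <- function(genic, exonic, gene_type = "protein_coding",
                         ids = sprintf("G%03d", seq_along(genic))) {
  snucnorm:::.new_gene_catalog(data.frame(
    gene_id = ids, chrom = "chr1", strand = "+",
    genic_length = as.integer(genic), exonic_length = as.integer(exonic),
    gene_type = rep_len(gene_type, length(genic)),
    stringsAsFactors = FALSE
  ))
}

# counts matrix with ids
make_counts <- function(values, source = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  expr_matrix(values, "counts", source = source)
}

# m_value_table built directly from covariates and M values
make_m_table <- function(t, e, M, mean_cell = 100, mean_nucleus = 100,
                         included = TRUE, pseudocount = 0.125) {
  df <- data.frame(
    gene_id = sprintf("G%05d", seq_along(M)),
    mean_cell = rep_len(mean_cell, length(M)),
    mean_nucleus = rep_len(mean_nucleus, length(M)),
    M = M, t = t, e = e,
    included = rep_len(included, length(M)),
    stringsAsFactors = FALSE
  )
  attr(df, "pseudocount") <- pseudocount
  attr(df, "detect_min_mean") <- 1
  class(df) <- c("m_value_table", "data.frame")
  df
}

# GTF line builder (tab-separated, 1-based inclusive)
gtf_line <- function(chrom, type, start, end, attrs, strand = "+") {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# per-base bitmap union length oracle for interval sets
bitmap_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  lo <- min(starts); hi <- max(ends)
  covered <- logical(hi - lo + 1)
  for (i in seq_along(starts))
    covered[(starts[i] - lo + 1):(ends[i] - lo + 1)] <- TRUE
  sum(covered)
}
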