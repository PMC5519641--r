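#' Merge genomic intervals into a disjoint sorted union
#'
#' Collapses a set of 1-based inclusive integer intervals into the minimal
#' sorted, pairwise-disjoint set covering the same bases. Touching intervals
#' (end + 1 == next start) are merged, matching per-base union semantics.
#'
#' @param intervals a two-column matrix or data frame of integer
#'   `(start, end)` pairs with `start <= end`, or an empty object.
#' @return a data frame with columns `start`, `end`, sorted and disjoint.
#' @examples
#' merge_intervals(cbind(c(1, 3, 10), c(5, 8, 12)))
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  intervals <- as.data.frame(intervals)
  if (ncol(intervals) < 2L) stop("`intervals` needs start and end columns")
  s <- as.integer(intervals[[1]]); e <- as.integer(intervals[[2]])
  if (any(is.na(s) | is.na(e))) stop("non-integer interval bounds")
  if (any(e < s)) stop("interval end < start")
  r <- IRanges::reduce(IRanges::IRanges(start = s, end = e))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

.mito_chroms <- c("chrM", "MT", "chrMT", "M", "mt")
.known_types <- c("protein_coding", "antisense", "Mt_rRNA", "Mt_tRNA", "lincRNA")

.new_gene_catalog <- function(df, exon_union = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "strand", "genic_length",
                  "exonic_length", "gene_type") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in catalog")
  if (any(df$exonic_length < 1)) stop("exonic_length < 1 in catalog")
  if (any(df$exonic_length > df$genic_length))
    stop("exonic_length > genic_length in catalog")
  df$intronic_fraction <- 1 - df$exonic_length / df$genic_length
  df$is_mito <- df$chrom %in% .mito_chroms |
    df$gene_type %in% c("Mt_rRNA", "Mt_tRNA")
  df <- df[, c("gene_id", "chrom", "strand", "genic_length", "exonic_length",
               "intronic_fraction", "gene_type", "is_mito")]
  rownames(df) <- NULL
  attr(df, "exon_union") <- exon_union
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Build a per-gene structural catalog from GTF annotation
#'
#' Derives, for every gene, the total genic span and the length of the union
#' of its exon intervals pooled across all transcripts. These are the two
#' covariates (on log10 scale) of the nuclear length-bias model: nascent
#' transcripts in the nucleus carry introns, so a gene's intronic fraction
#' `1 - exonic/genic` predicts its relative over-detection in nuclei.
#'
#' The gene span is taken from a `gene` feature line when the annotation has
#' one, otherwise from the extent of the gene's exons; if exons extend past
#' the gene line the span is widened to contain them. Exon lines lacking a
#' parseable `gene_id` are skipped with a warning and counted in the
#' `n_skipped` attribute. A feature line with end < start is a hard error.
#'
#' @param annotation path to a GTF/GFF file (Gencode dialect: attribute keys
#'   `gene_id` and `gene_type` or `gene_biotype`), or a character vector of
#'   GTF lines.
#' @return a `gene_catalog` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `genic_length`, `exonic_length`, `intronic_fraction`,
#'   `gene_type`, `is_mito`.
#' @export
parse_gene_lengths <- function(annotation) {
  path <- annotation
  if (length(annotation) > 1L || !file.exists(annotation[1])) {
    path <- tempfile(fileext = ".gtf")
    writeLines(annotation, path)
    on.exit(unlink(path))
  }
  # coordinate sanity pass: name the offending line before the real parse
  raw <- readLines(path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  fields <- strsplit(raw[body], "\t", fixed = TRUE)
  st <- suppressWarnings(vapply(fields, function(f) as.numeric(f[4]), 0))
  en <- suppressWarnings(vapply(fields, function(f) as.numeric(f[5]), 0))
  bad <- which(!is.na(st) & !is.na(en) & en < st)
  if (length(bad))
    stop(sprintf("annotation line %d has end < start: %s",
                 which(body)[bad[1]], raw[which(body)[bad[1]]]))

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc)) stop("annotation has no feature type column")
  ex <- gr[mc$type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon features")
  ex_gid <- S4Vectors::mcols(ex)$gene_id
  n_skipped <- sum(is.na(ex_gid) | ex_gid == "")
  if (n_skipped > 0) {
    warning(sprintf("%d exon record(s) without gene_id skipped", n_skipped))
    ex <- ex[!(is.na(ex_gid) | ex_gid == "")]
    ex_gid <- S4Vectors::mcols(ex)$gene_id
  }
  # exonic length: per-base union of exons pooled over all transcripts
  red <- GenomicRanges::reduce(S4Vectors::split(ex, ex_gid))
  exonic <- vapply(GenomicRanges::width(red), sum, 0)
  ex_ext_start <- vapply(GenomicRanges::start(red), min, 0)
  ex_ext_end <- vapply(GenomicRanges::end(red), max, 0)

  gid <- names(exonic)
  first_ex <- ex[match(gid, ex_gid)]
  chrom <- as.character(GenomicRanges::seqnames(first_ex))
  strand <- as.character(GenomicRanges::strand(first_ex))

  genic <- ex_ext_end - ex_ext_start + 1
  gene_rows <- gr[mc$type == "gene"]
  if (length(gene_rows)) {
    g_gid <- S4Vectors::mcols(gene_rows)$gene_id
    hit <- match(gid, g_gid)
    have <- !is.na(hit)
    span <- GenomicRanges::width(gene_rows)[hit[have]]
    genic[have] <- pmax(span, genic[have])
  }

  type_col <- intersect(c("gene_type", "gene_biotype"), names(mc))[1]
  gtype <- rep("other", length(gid))
  if (!is.na(type_col)) {
    tt <- S4Vectors::mcols(first_ex)[[type_col]]
    gtype <- ifelse(is.na(tt), "other",
                    ifelse(tt %in% .known_types, tt, "other"))
  }

  out <- .new_gene_catalog(data.frame(
    gene_id = gid, chrom = chrom, strand = strand,
    genic_length = as.integer(genic), exonic_length = as.integer(exonic),
    gene_type = gtype, stringsAsFactors = FALSE
  ))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read / write a gene catalog as TSV
#'
#' Column order is fixed: `gene_id`, `chrom`, `strand`, `genic_length`,
#' `exonic_length`, `intronic_fraction`, `gene_type`, `is_mito`. A minimal
#' 4-column file (`gene_id`, `genic_length`, `exonic_length`, `gene_type`)
#' is also accepted on read; missing positional fields are filled with
#' placeholders.
#'
#' @param catalog a `gene_catalog`.
#' @param path file path.
#' @return `read_gene_catalog` returns a `gene_catalog`;
#'   `write_gene_catalog` returns `path` invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_catalog
#' @export
read_gene_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"chrom" %in% names(df)) df$chrom <- "unknown"
  if (!"strand" %in% names(df)) df$strand <- "+"
  .new_gene_catalog(df)
}

.catalog_lookup <- function(catalog, gene_ids, what = "matrix") {
  idx <- match(gene_ids, catalog$gene_id)
  if (anyNA(idx)) {
    missing <- gene_ids[is.na(idx)]
    stop(sprintf("%d gene id(s) in %s missing from catalog: %s%s",
                 length(missing), what,
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  catalog[idx, , drop = FALSE]
}
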