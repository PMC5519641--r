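#' Validate a simulation/pipeline configuration
#'
#' Checks a configuration (a `sim_config`, a plain list, or a path to a
#' YAML/JSON file of overrides) and returns every violation at once rather
#' than stopping at the first. Unknown keys are warnings, not errors.
#'
#' @param config a `sim_config`, named list of overrides, or file path.
#' @return a list with `ok` (logical), `errors` (character vector),
#'   `warnings` (character vector), and the resolved `config`.
#' @export
validate_config <- function(config) {
  warnings <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!inherits(config, "sim_config")) {
    defaults <- sim_config()
    unknown <- setdiff(names(config), names(unclass(defaults)))
    if (length(unknown)) {
      warnings <- c(warnings, paste("unknown config key(s) ignored:",
                                    paste(unknown, collapse = ", ")))
      config <- config[setdiff(names(config), unknown)]
    }
    config <- do.call(sim_config, config)
  }
  errors <- character(0)
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(config$n_genes >= 1, "n_genes must be >= 1")
  chk(config$n_cells >= 2, "n_cells must be >= 2")
  chk(config$n_nuclei >= 2, "n_nuclei must be >= 2")
  chk(is.finite(config$seed), "seed must be a finite integer")
  chk(config$length_sdlog >= 0, "length_sdlog must be >= 0")
  chk(config$exonic_frac_sdlog >= 0, "exonic_frac_sdlog must be >= 0")
  chk(config$dispersion > 0, "dispersion must be positive")
  chk(config$libsize_sdlog >= 0, "libsize_sdlog must be >= 0")
  chk(config$m_noise_sd >= 0, "m_noise_sd must be >= 0")
  chk(config$divergent_fraction >= 0 && config$divergent_fraction <= 1,
      "divergent_fraction must be in [0, 1]")
  chk(config$dropout_rate >= 0 && config$dropout_rate <= 1,
      "dropout_rate must be in [0, 1]")
  chk(config$n_spikes >= 8, "n_spikes must be >= 8")
  chk(config$spike_decades >= 4, "spike_decades must be >= 4")
  chk(all(config$categ_means_cell > 0) && all(config$categ_means_nucleus > 0),
      "category means must be positive")
  chk(config$reads_per_cell >= 1, "reads_per_cell must be >= 1")
  chk(config$qc_min_genes >= 0, "qc_min_genes must be >= 0")
  chk(config$qc_min_cells >= 0, "qc_min_cells must be >= 0")
  list(ok = length(errors) == 0, errors = errors, warnings = warnings,
       config = config)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full simulate-qc-fit-correct-report pipeline
#'
#' Executes the whole analysis on synthetic paired nucleus/cell data:
#'
#' 1. **simulate** — gene catalog, paired count matrices with planted
#'    length bias, ERCC spikes, read-category tables;
#' 2. **qc** — TPM, cell filter (min genes at log2(TPM+1) >= threshold)
#'    then gene filter (min expressing cells), ERCC correlations,
#'    read-category proportions;
#' 3. **fit** — FPM on the filtered counts, per-gene M values between the
#'    averaged cell and nucleus profiles, 2-D smooth bias model;
#' 4. **correct** — multiplicative length-bias correction of the nuclear
#'    FPM matrix;
#' 5. **report** — differential detection and length-bias tests before and
#'    after correction, gene-type composition, `bias_removed` verdict.
#'
#' All stage outputs are written as TSV/JSON under `out_dir`; a manifest
#' with config snapshot, seed, per-stage timings and per-file digests is
#' written last. A stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config a `sim_config`, named list, or YAML/JSON path
#'   (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest` and the in-memory `results`
#'   of each stage.
#' @export
run_pipeline <- function(config, out_dir = tempfile("snucnorm_run_")) {
  val <- validate_config(config)
  for (w in val$warnings) warning(w, call. = FALSE)
  if (!val$ok)
    stop("invalid configuration:\n  - ",
         paste(val$errors, collapse = "\n  - "))
  config <- val$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  files <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sim <- stage("simulate", {
    catalog <- generate_catalog(config)
    counts <- generate_counts(catalog, config)
    ercc <- generate_ercc(config)
    categ_cell <- generate_read_categories(catalog, "cell", config)
    categ_nuc <- generate_read_categories(catalog, "nucleus", config)
    files <- c(files,
      write_gene_catalog(catalog, file.path(out_dir, "catalog.tsv")),
      write_expr_matrix(counts$cell, file.path(out_dir, "counts_cell.tsv")),
      write_expr_matrix(counts$nucleus, file.path(out_dir, "counts_nucleus.tsv")),
      .write_tsv(counts$truth, file.path(out_dir, "truth.tsv")),
      .write_tsv(ercc$reference, file.path(out_dir, "ercc_reference.tsv")),
      write_expr_matrix(ercc$counts, file.path(out_dir, "ercc_counts.tsv")),
      .write_tsv(data.frame(cell_id = rownames(categ_cell), categ_cell),
                 file.path(out_dir, "read_categories_cell.tsv")),
      .write_tsv(data.frame(cell_id = rownames(categ_nuc), categ_nuc),
                 file.path(out_dir, "read_categories_nucleus.tsv")))
    list(catalog = catalog, counts = counts, ercc = ercc,
         categ_cell = categ_cell, categ_nuc = categ_nuc)
  })

  qc <- stage("qc", {
    tpm_cell <- counts_to_tpm(sim$counts$cell, sim$catalog)
    tpm_nuc <- counts_to_tpm(sim$counts$nucleus, sim$catalog)
    fc_cell <- filter_cells(tpm_cell, min_genes = config$qc_min_genes,
                            expr_threshold = config$qc_expr_threshold)
    fc_nuc <- filter_cells(tpm_nuc, min_genes = config$qc_min_genes,
                           expr_threshold = config$qc_expr_threshold)
    # gene filter on the pooled kept cells so both matrices keep one universe
    pooled <- expr_matrix(
      cbind(fc_cell$matrix$values, fc_nuc$matrix$values), "TPM")
    fg <- filter_genes(pooled, min_cells = config$qc_min_cells,
                       expr_threshold = config$qc_expr_threshold)
    kept_genes <- fg$report$gene_id[fg$report$kept]
    kept_cells_c <- em_cells(fc_cell$matrix)
    kept_cells_n <- em_cells(fc_nuc$matrix)
    spike_tpm <- ercc_tpm(sim$ercc$counts)
    ercc_r <- ercc_correlation(spike_tpm, sim$ercc$reference)
    props_cell <- region_proportions(sim$categ_cell)
    props_nuc <- region_proportions(sim$categ_nuc)
    files <- c(files,
      .write_tsv(fc_cell$report, file.path(out_dir, "qc_cells_cell.tsv")),
      .write_tsv(fc_nuc$report, file.path(out_dir, "qc_cells_nucleus.tsv")),
      .write_tsv(fg$report, file.path(out_dir, "qc_genes.tsv")),
      .write_tsv(ercc_r, file.path(out_dir, "ercc_correlation.tsv")))
    list(kept_genes = kept_genes, kept_cells_cell = kept_cells_c,
         kept_cells_nuc = kept_cells_n, ercc_r = ercc_r,
         props_cell = props_cell, props_nuc = props_nuc)
  })

  fit_res <- stage("fit", {
    cell_counts <- sim$counts$cell[qc$kept_genes, qc$kept_cells_cell]
    nuc_counts <- sim$counts$nucleus[qc$kept_genes, qc$kept_cells_nuc]
    fpm_cell <- counts_to_fpm(cell_counts)
    fpm_nuc <- counts_to_fpm(nuc_counts)
    mtab <- compute_m_values(fpm_cell, fpm_nuc, sim$catalog)
    fit <- fit_bias_model(mtab)
    files <- c(files,
      .write_tsv(as.data.frame(mtab), file.path(out_dir, "m_values.tsv")),
      write_bias_fit(fit, file.path(out_dir, "bias_fit.json")))
    list(fpm_cell = fpm_cell, fpm_nuc = fpm_nuc, mtab = mtab, fit = fit)
  })

  corrected <- stage("correct", {
    corr <- apply_correction(fit_res$fpm_nuc, fit_res$fit, sim$catalog)
    files <- c(files,
      write_expr_matrix(corr, file.path(out_dir, "corrected_nucleus.tsv")))
    corr
  })

  report <- stage("report", {
    log_cell <- log1p_expr(fit_res$fpm_cell)
    pre <- differential_detection(log_cell, log1p_expr(fit_res$fpm_nuc))
    post <- differential_detection(log_cell, log1p_expr(corrected))
    split_sets <- function(res) list(
      up = res$gene_id[res$passes & res$direction == "up_in_cells"],
      down = res$gene_id[res$passes & res$direction == "up_in_nuclei"])
    pre_sets <- split_sets(pre)
    post_sets <- split_sets(post)
    pre_bias <- length_bias_test(pre_sets$up, pre_sets$down, sim$catalog,
                                 stage = "before")
    post_bias <- length_bias_test(post_sets$up, post_sets$down, sim$catalog,
                                  stage = "after")
    ba <- before_after_report(pre, post, pre_bias, post_bias)
    comp <- gene_type_composition(
      expr_matrix(cbind(sim$counts$cell$values, sim$counts$nucleus$values),
                  "counts",
                  source = c(rep("cell", config$n_cells),
                             rep("nucleus", config$n_nuclei))),
      sim$catalog)
    summary <- list(
      n_genes_fit = nrow(fit_res$fit$train),
      variance_explained = fit_res$fit$variance_explained,
      edf = fit_res$fit$edf, lambda = fit_res$fit$lambda,
      mean_ercc_r = mean(qc$ercc_r$r, na.rm = TRUE),
      pre = list(n_pass = sum(pre$passes),
                 student_t_p = pre_bias$student_t_p,
                 wilcoxon_p = pre_bias$wilcoxon_p),
      post = list(n_pass = sum(post$passes),
                  student_t_p = post_bias$student_t_p,
                  wilcoxon_p = post_bias$wilcoxon_p),
      bias_removed = ba$bias_removed
    )
    sfile <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, sfile, auto_unbox = TRUE, digits = NA)
    files <- c(files,
      .write_tsv(as.data.frame(pre),
                 file.path(out_dir, "diff_detection_before.tsv")),
      .write_tsv(as.data.frame(post),
                 file.path(out_dir, "diff_detection_after.tsv")),
      .write_tsv(comp$per_cell, file.path(out_dir, "gene_type_composition.tsv")),
      sfile)
    list(pre = pre, post = post, pre_bias = pre_bias, post_bias = post_bias,
         before_after = ba, composition = comp, summary = summary)
  })

  manifest <- list(
    tool = "snucnorm",
    version = as.character(utils::packageVersion("snucnorm")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.function, TRUE)],
    timings_sec = timings,
    outputs = lapply(files, function(f) list(
      path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  mfile <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mfile, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, out_dir = out_dir, results = list(
    sim = sim, qc = qc, fit = fit_res, corrected = corrected,
    report = report)))
}
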