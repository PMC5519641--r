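#' Simulation configuration for paired nucleus/cell data
#'
#' Returns the default configuration of the synthetic-data generator, with
#' any field overridden by name. The generator emulates the statistical
#' structure of a paired single-nucleus / single-cell experiment:
#'
#' * gene structure: genic length log-normal (default median 20 kb,
#'   sdlog 1.5), exonic fraction log-normal (default median 0.15), giving
#'   the long, intron-rich gene population typical of a mammalian brain
#'   transcriptome;
#' * expression: per-gene rates log-normal, per-cell library sizes
#'   log-normal, negative-binomial counts with size `dispersion`;
#' * planted bias: the expected log2 cell/nucleus ratio of gene g is
#'   `f(t_g, e_g) + delta_g + eta_g`, where `f` is the planted smooth
#'   surface (default linear in log10 genic length and intronic fraction,
#'   negative slope: long intron-rich genes are relatively higher in
#'   nuclei), `delta_g` is a one-sided biological divergence applied to a
#'   random gene subset (higher in cells), and `eta_g ~ N(0, m_noise_sd)`
#'   is gene-level biological scatter unrelated to length;
#' * ERCC spike-ins with inputs spanning several orders of magnitude and
#'   noisy per-cell capture;
#' * per-cell read-category tables (CDS exon / intron / 3'UTR / 5'UTR)
#'   drawn from source-specific Dirichlet means, nuclei intron-rich.
#'
#' @param ... named overrides of the default fields.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 5000L, n_cells = 100L, n_nuclei = 100L, seed = 1L,
    # gene structure model
    length_meanlog = log(2e4), length_sdlog = 1.5,
    exonic_frac_meanlog = log(0.15), exonic_frac_sdlog = 0.8,
    type_probs = c(protein_coding = 0.85, antisense = 0.05, lincRNA = 0.06,
                   Mt_rRNA = 0.005, Mt_tRNA = 0.005, other = 0.03),
    # expression + noise model
    expr_meanlog = log(300), expr_sdlog = 1.5,
    dispersion = 2, libsize_sdlog = 0.3,
    dropout_rate = 0,
    # planted bias surface f(t, e) = a*(log10 t - t0) + b*(ifrac - i0)
    bias_a = -0.9, bias_b = -1.5,
    bias_center_t = log10(2e4), bias_center_i = 0.85,
    bias_surface = NULL,   # optional function(log10_genic, intronic_frac)
    m_noise_sd = 0.5,
    divergent_fraction = 0.05, divergent_effect = 2,
    # ERCC spike-ins
    n_spikes = 64L, spike_decades = 5, spike_total = 25000,
    spike_noise_sd = 1.7, spike_eff_sdlog = 0.2,
    # QC filter thresholds (standard inclusion rules for these data)
    qc_min_genes = 1000, qc_expr_threshold = 1, qc_min_cells = 3,
    # read categories
    reads_per_cell = 1e6,
    categ_conc = 100,
    categ_means_cell = c(cds_exon = 0.45, intron = 0.22,
                         utr3 = 0.22, utr5 = 0.11),
    categ_means_nucleus = c(cds_exon = 0.22, intron = 0.60,
                            utr3 = 0.12, utr5 = 0.06)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$n_genes <- as.integer(cfg$n_genes)
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$n_nuclei <- as.integer(cfg$n_nuclei)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Evaluate the planted bias surface on a catalog
#'
#' Returns the planted expected log2 cell/nucleus ratio component driven by
#' gene structure: `f(t, e)` evaluated at each gene's log10 genic length and
#' intronic fraction. This is the ground-truth signal the bias model is
#' asked to recover.
#'
#' @param catalog a `gene_catalog`.
#' @param config a `sim_config`.
#' @return numeric vector, one value per catalog row (log2 units).
#' @export
planted_bias <- function(catalog, config) {
  t10 <- log10(catalog$genic_length)
  ifrac <- catalog$intronic_fraction
  f <- if (is.function(config$bias_surface)) {
    config$bias_surface(t10, ifrac)
  } else {
    config$bias_a * (t10 - config$bias_center_t) +
      config$bias_b * (ifrac - config$bias_center_i)
  }
  if (any(!is.finite(f)))
    stop("bias surface evaluates non-finite on ",
         sum(!is.finite(f)), " gene(s)")
  f
}

#' Generate a synthetic gene catalog
#'
#' Draws genic lengths and exonic fractions from the configured log-normal
#' models and assigns gene types by the configured probabilities
#' (mitochondrial types are placed on chrM). Fully determined by
#' `config$seed`.
#'
#' @param config a `sim_config`.
#' @return a `gene_catalog`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) stop("n_genes must be >= 1")
  if (!is.finite(config$length_meanlog) || config$length_sdlog < 0 ||
      exp(config$length_meanlog) <= 0)
    stop("degenerate length model: nonpositive or non-finite scale")
  set.seed(config$seed)
  n <- config$n_genes
  genic <- pmax(200L, as.integer(round(
    stats::rlnorm(n, config$length_meanlog, config$length_sdlog))))
  efrac <- pmin(1, pmax(5e-3, stats::rlnorm(
    n, config$exonic_frac_meanlog, config$exonic_frac_sdlog)))
  exonic <- pmax(1L, pmin(genic, as.integer(round(genic * efrac))))
  tp <- config$type_probs / sum(config$type_probs)
  gtype <- sample(names(tp), n, replace = TRUE, prob = tp)
  chrom <- sample(c(paste0("chr", 1:19), "chrX"), n, replace = TRUE)
  chrom[gtype %in% c("Mt_rRNA", "Mt_tRNA")] <- "chrM"
  .new_gene_catalog(data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = chrom,
    strand = sample(c("+", "-"), n, replace = TRUE),
    genic_length = genic, exonic_length = exonic,
    gene_type = gtype, stringsAsFactors = FALSE
  ))
}

.rnb <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Generate paired nucleus/cell count matrices with known truth
#'
#' Cell counts are NB with mean `lambda_g * s_c`; nucleus counts are NB with
#' mean `lambda_g * s_c * 2^-(f_g + delta_g + eta_g)`, so the expected
#' log2(cell/nucleus) ratio of gene g is `f_g + delta_g + eta_g`:
#' the planted length-bias surface, plus a one-sided divergence `delta` for
#' a random subset of genes (emulating transcripts genuinely enriched in
#' the cytosol), plus length-independent gene-level scatter `eta`. Optional
#' independent Bernoulli dropout zeroes entries post-sampling.
#'
#' @param catalog a `gene_catalog`, typically from [generate_catalog()].
#' @param config a `sim_config`.
#' @return a list with elements `cell` and `nucleus` (counts
#'   `expr_matrix` objects) and `truth`, a data frame with per-gene
#'   `bias` (the planted surface value f), `delta`, `divergent`, `m_noise`
#'   (eta), `base_expression` and `expected_m = bias + delta + m_noise`;
#'   the configuration is attached as attribute `config`.
#' @export
generate_counts <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "sim_config"))
  n <- nrow(catalog)
  if (n == 0L) stop("empty catalog")
  if (config$n_cells < 2L || config$n_nuclei < 2L)
    stop("need at least 2 cells and 2 nuclei")
  f <- planted_bias(catalog, config)   # errors on non-finite before sampling
  set.seed(config$seed + 1L)
  lambda <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  n_div <- round(config$divergent_fraction * n)
  div_idx <- sort(sample.int(n, n_div))
  delta <- numeric(n); delta[div_idx] <- config$divergent_effect
  eta <- if (config$m_noise_sd > 0) stats::rnorm(n, 0, config$m_noise_sd) else numeric(n)
  m_true <- f + delta + eta

  s_cell <- stats::rlnorm(config$n_cells, 0, config$libsize_sdlog)
  s_nuc <- stats::rlnorm(config$n_nuclei, 0, config$libsize_sdlog)
  mu_cell <- outer(lambda, s_cell)
  mu_nuc <- outer(lambda * 2^(-m_true), s_nuc)
  cells <- matrix(.rnb(length(mu_cell), mu_cell, config$dispersion),
                  nrow = n, dimnames = list(
                    catalog$gene_id, sprintf("cell_%04d", seq_len(config$n_cells))))
  nucs <- matrix(.rnb(length(mu_nuc), mu_nuc, config$dispersion),
                 nrow = n, dimnames = list(
                   catalog$gene_id, sprintf("nuc_%04d", seq_len(config$n_nuclei))))
  if (config$dropout_rate > 0) {
    cells <- cells * matrix(stats::rbinom(length(cells), 1, 1 - config$dropout_rate),
                            nrow = n)
    nucs <- nucs * matrix(stats::rbinom(length(nucs), 1, 1 - config$dropout_rate),
                          nrow = n)
  }
  truth <- data.frame(
    gene_id = catalog$gene_id,
    bias = f, delta = delta, divergent = seq_len(n) %in% div_idx,
    m_noise = eta, expected_m = m_true, base_expression = lambda,
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- config
  list(
    cell = expr_matrix(cells, "counts",
                       source = rep("cell", config$n_cells)),
    nucleus = expr_matrix(nucs, "counts",
                          source = rep("nucleus", config$n_nuclei)),
    truth = truth
  )
}

#' Generate ERCC spike-in reference and counts
#'
#' Spike input quantities form a geometric series over
#' `spike_decades` orders of magnitude. Per cell, spike counts are NB with
#' mean proportional to input quantity times a per-cell capture efficiency,
#' with multiplicative log-normal spike-by-cell noise (`spike_noise_sd`, on
#' the natural-log scale) controlling how faithful the observed dose
#' response is.
#'
#' @param config a `sim_config`.
#' @param cell_ids optional character vector of cell ids; default
#'   `n_cells + n_nuclei` ids matching [generate_counts()].
#' @return a list with `reference` (data frame `spike_id`,
#'   `input_quantity`) and `counts` (spikes x cells `expr_matrix`).
#' @export
generate_ercc <- function(config, cell_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_spikes < 8L) stop("need at least 8 spike species")
  if (config$spike_decades < 4) stop("spike inputs must span >= 4 decades")
  set.seed(config$seed + 2L)
  if (is.null(cell_ids))
    cell_ids <- c(sprintf("cell_%04d", seq_len(config$n_cells)),
                  sprintf("nuc_%04d", seq_len(config$n_nuclei)))
  q <- 10^seq(0, config$spike_decades, length.out = config$n_spikes)
  ids <- sprintf("ERCC-%05d", seq_len(config$n_spikes))
  eff <- stats::rlnorm(length(cell_ids), 0, config$spike_eff_sdlog)
  base <- config$spike_total * q / sum(q)
  mu <- outer(base, eff)
  if (config$spike_noise_sd > 0)
    mu <- mu * matrix(stats::rlnorm(length(mu), 0, config$spike_noise_sd),
                      nrow = length(q))
  counts <- matrix(.rnb(length(mu), mu, config$dispersion),
                   nrow = length(q), dimnames = list(ids, cell_ids))
  list(
    reference = data.frame(spike_id = ids, input_quantity = q,
                           stringsAsFactors = FALSE),
    counts = expr_matrix(counts, "counts")
  )
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}

# integer apportionment by largest remainder so rows sum exactly to total
.apportion <- function(p, total) {
  raw <- p * total
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate per-cell read-category count tables
#'
#' Emulates the mapping-category summary of an alignment (CDS exon, intron,
#' 3'UTR, 5'UTR) per cell: category proportions are Dirichlet with
#' source-specific means (nuclei draw a substantially higher intron share,
#' reflecting nascent transcripts) and concentration `categ_conc`
#' (`Inf` gives the means exactly); counts are apportioned so every row
#' sums exactly to `reads_per_cell`.
#'
#' @param catalog a `gene_catalog` (validated; category totals do not depend
#'   on individual genes).
#' @param source `"cell"` or `"nucleus"`.
#' @param config a `sim_config`.
#' @return an integer matrix, cells x categories, with cell ids as rownames.
#' @export
generate_read_categories <- function(catalog, source = c("cell", "nucleus"),
                                     config) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "sim_config"))
  source <- match.arg(source)
  set.seed(config$seed + if (source == "cell") 3L else 4L)
  n <- if (source == "cell") config$n_cells else config$n_nuclei
  ids <- if (source == "cell") sprintf("cell_%04d", seq_len(n))
         else sprintf("nuc_%04d", seq_len(n))
  means <- if (source == "cell") config$categ_means_cell
           else config$categ_means_nucleus
  means <- means / sum(means)
  p <- if (is.infinite(config$categ_conc)) {
    matrix(means, nrow = n, ncol = length(means), byrow = TRUE)
  } else {
    .rdirichlet(n, config$categ_conc * means)
  }
  out <- t(apply(p, 1, .apportion, total = config$reads_per_cell))
  dimnames(out) <- list(ids, names(means))
  out
}

#' Calibrate gene-level scatter for a target surface variance fraction
#'
#' Chooses `m_noise_sd` so that the planted surface accounts for a target
#' fraction `rho` of the variance of observed per-gene M values:
#' `rho = Var(f) / (Var(f) + m_noise_sd^2 + v_sampling)`. `Var(f)` is taken
#' empirically over the catalog; the sampling variance of M (from averaging
#' NB counts over finitely many cells) is approximated analytically as
#' `2 * (E[1/lambda] + 1/size) / (n_cells * ln(2)^2)` using the configured
#' log-normal rate model.
#'
#' @param catalog a `gene_catalog`.
#' @param config a `sim_config`.
#' @param rho target variance fraction in (0, 1).
#' @return a `sim_config` equal to `config` with `m_noise_sd` replaced.
#' @export
calibrate_m_noise <- function(catalog, config, rho) {
  stopifnot(inherits(config, "sim_config"), rho > 0, rho < 1)
  vf <- stats::var(planted_bias(catalog, config))
  e_inv_lambda <- exp(-config$expr_meanlog + config$expr_sdlog^2 / 2)
  n_avg <- (config$n_cells + config$n_nuclei) / 2
  v_samp <- 2 * (e_inv_lambda + 1 / config$dispersion) /
    (n_avg * log(2)^2)
  v_noise <- max(0, vf * (1 - rho) / rho - v_samp)
  config$m_noise_sd <- sqrt(v_noise)
  config
}
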