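#' Per-gene M values between matched cell and nucleus profiles
#'
#' Averages expression across the cells of each matrix and computes, per
#' gene, the log2 fold expression ratio
#' `M = log2((mean_cell + c) / (mean_nucleus + c))` with pseudocount `c`.
#' Positive M means higher expression in whole cells than in nuclei.
#' The structural covariates of the bias model, `t = log10(genic length)`
#' and `e = log10(exonic length)`, are attached from the catalog; since
#' exonic length never exceeds genic length, `e <= t` holds for every row.
#' A gene enters the model-fitting set (`included`) when its mean
#' expression reaches `detect_min_mean` in either population.
#'
#' @param cell_matrix `expr_matrix` of whole-cell expression, layer `FPM`.
#' @param nuc_matrix `expr_matrix` of nuclear expression, layer `FPM` or
#'   `correctedFPM`.
#' @param catalog a `gene_catalog`.
#' The pseudocount defaults to 1/8 FPM: it must be small relative to the
#' expression of genes near the detection threshold, because a pseudocount
#' comparable to the means shrinks M toward zero for weakly expressed
#' genes; a surface fitted to such attenuated M values systematically
#' under-corrects, leaving a residual length bias proportional to the
#' planted one.
#'
#' @param pseudocount pseudocount `c` added to both means, default 0.125.
#' @param detect_min_mean detection threshold on the mean (FPM), default 1.
#' @return a data frame of class `m_value_table` with columns `gene_id`,
#'   `mean_cell`, `mean_nucleus`, `M`, `t`, `e`, `included`.
#' @export
compute_m_values <- function(cell_matrix, nuc_matrix, catalog,
                             pseudocount = 0.125, detect_min_mean = 1) {
  .check_layer(cell_matrix, c("FPM", "correctedFPM"), "cell_matrix")
  .check_layer(nuc_matrix, c("FPM", "correctedFPM"), "nuc_matrix")
  if (ncol(cell_matrix$values) == 0L || ncol(nuc_matrix$values) == 0L)
    stop("empty expression matrix")
  shared <- intersect(em_genes(cell_matrix), em_genes(nuc_matrix))
  if (length(shared) == 0L)
    stop("cell and nucleus matrices share no genes")
  mc <- rowMeans(cell_matrix$values[shared, , drop = FALSE])
  mn <- rowMeans(nuc_matrix$values[shared, , drop = FALSE])
  cat_rows <- .catalog_lookup(catalog, shared, "M-value table")
  out <- data.frame(
    gene_id = shared,
    mean_cell = mc, mean_nucleus = mn,
    M = log2((mc + pseudocount) / (mn + pseudocount)),
    t = log10(cat_rows$genic_length),
    e = log10(cat_rows$exonic_length),
    included = mc >= detect_min_mean | mn >= detect_min_mean,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  stopifnot(all(out$e <= out$t))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "detect_min_mean") <- detect_min_mean
  attr(out, "orientation") <- "positive M = higher in whole cells"
  class(out) <- c("m_value_table", "data.frame")
  out
}

# cubic B-spline basis on equally spaced knots extended beyond the range,
# k basis functions (k >= 4)
.bspline_knots <- function(rng, k) {
  if (k < 4) stop("basis dimension must be >= 4 per margin")
  if (diff(rng) <= 0)
    stop("degenerate covariate (no spread); a 2-D surface cannot be fit ",
         "- consider a 1-D model")
  dx <- diff(rng) / (k - 3)
  seq(rng[1] - 3 * dx, rng[2] + 3 * dx, by = dx)
}

.bspline_eval <- function(knots, x) {
  splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
}

# row-wise Kronecker (tensor) product of two marginal bases
.tensor_basis <- function(Bt, Be) {
  kt <- ncol(Bt); ke <- ncol(Be)
  Bt[, rep(seq_len(kt), each = ke), drop = FALSE] *
    Be[, rep(seq_len(ke), times = kt), drop = FALSE]
}

# second-order difference penalty for the tensor coefficients
.tensor_penalty <- function(kt, ke) {
  Dt <- diff(diag(kt), differences = 2)
  De <- diff(diag(ke), differences = 2)
  kronecker(crossprod(Dt), diag(ke)) + kronecker(diag(kt), crossprod(De))
}

#' Fit the 2-D smooth length-bias model M ~ s(t, e)
#'
#' Fits a smooth surface to per-gene M values as a function of log10 genic
#' length `t` and log10 exonic length `e`, with Gaussian errors and
#' identity link: a tensor-product cubic B-spline surface (basis dimension
#' `k` per margin) with second-order difference penalties on the
#' coefficients and a single smoothing parameter `lambda` shared by both
#' margins. When `lambda` is `NULL` it is chosen by generalized
#' cross-validation over a fixed logarithmic grid; the fit is fully
#' deterministic. `lambda = 0` gives the unpenalized least-squares fit on
#' the same basis.
#'
#' Genes are weighted uniformly by default. Weighting by an estimate of
#' each gene's M precision is deliberately not offered: such weights depend
#' on the observed means and hence on each gene's own biological deviation
#' from the surface, which selects against deviating genes and biases the
#' fitted surface.
#'
#' Variance explained is `1 - RSS/TSS` over the fitted genes (unweighted;
#' 0 when M is constant).
#'
#' @param table an `m_value_table`; only rows with `included = TRUE` are
#'   fitted.
#' @param k marginal basis dimension, a single integer (default 5, i.e. 25
#'   tensor coefficients) or a length-2 vector `(k_t, k_e)`.
#' @param lambda fixed smoothing parameter, or `NULL` for GCV selection.
#' @param lambda_grid grid searched by GCV.
#' @param weights optional numeric vector of positive per-gene weights
#'   aligned with the included rows; default uniform.
#' @param min_genes minimum number of included genes, default 50.
#' @return an object of class `bias_fit` with elements `coef`, `lambda`,
#'   `edf` (effective degrees of freedom), `fitted`, `residuals`,
#'   `variance_explained`, `hull` (training covariate ranges), `gcv_table`,
#'   and the training table.
#' @export
fit_bias_model <- function(table, k = 5, lambda = NULL,
                           lambda_grid = 10^seq(-8, 6, length.out = 57),
                           weights = NULL,
                           min_genes = 50) {
  stopifnot(inherits(table, "m_value_table"))
  tr <- table[table$included, , drop = FALSE]
  n <- nrow(tr)
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
      stop("`weights` must be positive and match the included rows")
    w <- weights / mean(weights)
  }
  if (n < min_genes)
    stop(sprintf("only %d included genes; need >= %d to fit", n, min_genes))
  if (length(k) == 1L) k <- c(k, k)
  kt <- as.integer(k[1]); ke <- as.integer(k[2])
  if (kt * ke > n)
    stop(sprintf("basis dimension %d x %d exceeds the %d included genes",
                 kt, ke, n))
  if (stats::sd(tr$t) == 0)
    stop("all t values equal; a 2-D surface cannot be fit - consider a 1-D model")
  if (stats::sd(tr$e) == 0)
    stop("all e values equal; a 2-D surface cannot be fit - consider a 1-D model")

  hull <- list(t = range(tr$t), e = range(tr$e))
  knots_t <- .bspline_knots(hull$t, kt)
  knots_e <- .bspline_knots(hull$e, ke)
  B <- .tensor_basis(.bspline_eval(knots_t, tr$t), .bspline_eval(knots_e, tr$e))
  P <- .tensor_penalty(kt, ke)
  BtWB <- crossprod(B, w * B)
  BtWy <- crossprod(B, w * tr$M)

  solve_one <- function(lam) {
    A <- BtWB + lam * P
    coef <- tryCatch(solve(A, BtWy), error = function(e) NULL)
    if (is.null(coef)) return(NULL)
    fitted <- drop(B %*% coef)
    wrss <- sum(w * (tr$M - fitted)^2)
    edf <- sum(diag(solve(A, BtWB)))
    list(coef = drop(coef), fitted = fitted, wrss = wrss, edf = edf,
         gcv = n * wrss / (n - edf)^2)
  }

  gcv_table <- NULL
  if (is.null(lambda)) {
    fits <- lapply(lambda_grid, solve_one)
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) stop("no smoothing parameter on the grid gave a stable fit")
    gcv <- vapply(fits, function(f) if (is.null(f)) Inf else f$gcv, 0)
    best <- which.min(gcv)
    lambda <- lambda_grid[best]
    fit <- fits[[best]]
    gcv_table <- data.frame(lambda = lambda_grid, gcv = gcv,
                            edf = vapply(fits, function(f)
                              if (is.null(f)) NA_real_ else f$edf, 0))
  } else {
    fit <- solve_one(lambda)
    if (is.null(fit))
      stop("normal equations singular at the requested lambda; ",
           "increase lambda or reduce k")
  }

  rss <- sum((tr$M - fit$fitted)^2)
  tss <- sum((tr$M - mean(tr$M))^2)
  ve <- if (tss < 1e-10) 0 else max(0, min(1, 1 - rss / tss))
  structure(list(
    k = c(t = kt, e = ke), knots_t = knots_t, knots_e = knots_e,
    coef = fit$coef, lambda = lambda, edf = fit$edf,
    fitted = fit$fitted, residuals = tr$M - fit$fitted,
    weights = w,
    variance_explained = ve, rss = rss, tss = tss,
    hull = hull, gcv_table = gcv_table,
    selection = if (is.null(gcv_table)) "fixed" else "GCV",
    train = tr
  ), class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf(
    "bias_fit: tensor-product P-spline s(t, e), %d x %d basis\n", x$k[1], x$k[2]))
  cat(sprintf("  genes fitted: %d | lambda = %.4g (%s) | edf = %.2f\n",
              nrow(x$train), x$lambda, x$selection, x$edf))
  cat(sprintf("  variance explained: %.3f\n", x$variance_explained))
  invisible(x)
}

#' Evaluate the fitted bias surface
#'
#' Evaluates the fitted surface at covariates `(t, e)` (log10 genic and
#' exonic lengths). Queries outside the training covariate hull are clamped
#' to the hull boundary before evaluation — the correction never
#' extrapolates the spline beyond the lengths it was fitted on.
#'
#' @param fit a `bias_fit`.
#' @param t numeric vector, log10 genic length.
#' @param e numeric vector, log10 exonic length (recycled with `t`).
#' @return numeric vector of predicted M values.
#' @export
predict_bias <- function(fit, t, e) {
  stopifnot(inherits(fit, "bias_fit"))
  if (any(!is.finite(t)) || any(!is.finite(e)))
    stop("non-finite covariates in prediction")
  nn <- max(length(t), length(e))
  t <- rep_len(t, nn); e <- rep_len(e, nn)
  t <- pmin(pmax(t, fit$hull$t[1]), fit$hull$t[2])
  e <- pmin(pmax(e, fit$hull$e[1]), fit$hull$e[2])
  B <- .tensor_basis(.bspline_eval(fit$knots_t, t),
                     .bspline_eval(fit$knots_e, e))
  drop(B %*% fit$coef)
}

#' @export
predict.bias_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_bias(object, newdata$t, newdata$e)
}

#' Correct nuclear expression for the length bias
#'
#' Multiplies each gene's nuclear expression by `2^Mhat(t_g, e_g)`, the
#' bias the surface predicts for its length covariates, so that genes
#' obeying the surface have an expected post-correction cell/nucleus log2
#' ratio of 0. Zeros map to zeros; the layer becomes `correctedFPM`.
#' Genes outside the training hull are corrected with the clamped boundary
#' prediction.
#'
#' @param nuc_matrix nuclear `expr_matrix`, layer `FPM`.
#' @param fit a `bias_fit`.
#' @param catalog a `gene_catalog` covering every gene.
#' @return an `expr_matrix` with layer `correctedFPM`.
#' @export
apply_correction <- function(nuc_matrix, fit, catalog) {
  .check_layer(nuc_matrix, "FPM", "nuc_matrix")
  stopifnot(inherits(fit, "bias_fit"))
  cat_rows <- .catalog_lookup(catalog, em_genes(nuc_matrix), "nuclear matrix")
  mhat <- predict_bias(fit, log10(cat_rows$genic_length),
                       log10(cat_rows$exonic_length))
  corrected <- nuc_matrix$values * 2^mhat
  out <- expr_matrix(corrected, "correctedFPM",
                     source = nuc_matrix$source, cluster = nuc_matrix$cluster)
  attr(out, "mhat") <- stats::setNames(mhat, em_genes(nuc_matrix))
  out
}

#' Variance explained by the bias surface
#'
#' Reports the fraction of M-variance captured by the fitted smooth
#' (`1 - RSS/TSS` on the fitted genes) together with the effective degrees
#' of freedom and smoothing parameter.
#'
#' @param fit a `bias_fit`.
#' @return a list with `variance_explained`, `edf`, `lambda`, `n_genes`,
#'   and a one-line `summary` string.
#' @export
variance_explained_report <- function(fit) {
  stopifnot(inherits(fit, "bias_fit"))
  list(
    variance_explained = fit$variance_explained,
    edf = fit$edf,
    lambda = fit$lambda,
    n_genes = nrow(fit$train),
    summary = sprintf(
      "smooth s(t, e) explains %.1f%% of M-variance (%d genes, edf %.1f, lambda %.3g)",
      100 * fit$variance_explained, nrow(fit$train), fit$edf, fit$lambda)
  )
}

#' Read / write a bias-model fit as plain text
#'
#' Self-describing JSON serialisation of the fitted surface (knots,
#' coefficients, smoothing parameter, hull, variance explained) sufficient
#' to reproduce predictions exactly.
#'
#' @param fit a `bias_fit`.
#' @param path file path.
#' @return `read_bias_fit` returns a `bias_fit` (prediction-complete;
#'   training rows are not stored); `write_bias_fit` returns `path`
#'   invisibly.
#' @export
write_bias_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bias_fit"))
  obj <- list(
    format = "snucnorm_bias_fit", version = 1L,
    k = as.integer(fit$k), knots_t = fit$knots_t, knots_e = fit$knots_e,
    coef = fit$coef, lambda = fit$lambda, edf = fit$edf,
    variance_explained = fit$variance_explained,
    hull = fit$hull, selection = fit$selection,
    n_train = nrow(fit$train)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bias_fit
#' @export
read_bias_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "snucnorm_bias_fit"))
    stop("not a snucnorm bias-fit file: ", path)
  structure(list(
    k = stats::setNames(as.integer(obj$k), c("t", "e")),
    knots_t = obj$knots_t, knots_e = obj$knots_e,
    coef = obj$coef, lambda = obj$lambda, edf = obj$edf,
    fitted = NULL, residuals = NULL,
    variance_explained = obj$variance_explained,
    hull = list(t = obj$hull$t, e = obj$hull$e),
    gcv_table = NULL, selection = obj$selection,
    train = data.frame(gene_id = rep(NA_character_, obj$n_train))
  ), class = "bias_fit")
}
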