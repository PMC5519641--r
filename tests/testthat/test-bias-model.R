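test_that("compute_m_values applies the pseudocount log-ratio with covariates", {
  catal <- make_catalog(c(10000, 20000, 40000), c(2000, 3000, 4000))
  cellv <- matrix(c(3, 5, 0), 3, 2, dimnames = list(catal$gene_id, c("a", "b")))
  nucv <- matrix(c(1, 5, 0), 3, 2, dimnames = list(catal$gene_id, c("x", "y")))
  mc <- expr_matrix(cellv, "FPM"); mn <- expr_matrix(nucv, "FPM")
  mt <- compute_m_values(mc, mn, catal, pseudocount = 1)
  # mean_cell = 3, mean_nuc = 1, c = 1: M = log2(4/2) = 1
  expect_equal(mt$M[1], 1)
  # equal means: M = 0
  expect_equal(mt$M[2], 0)
  # absent in both with c = 1: M = 0 and excluded from fitting
  expect_equal(mt$M[3], 0)
  expect_false(mt$included[3])
  expect_true(all(mt$included[1:2]))
  expect_equal(mt$t, log10(catal$genic_length))
  expect_equal(mt$e, log10(catal$exonic_length))
  expect_true(all(mt$e <= mt$t))
  expect_error(compute_m_values(mc, expr_matrix(
    matrix(1, 1, 2, dimnames = list("other", c("x", "y"))), "FPM"), catal),
    "no genes")
})

test_that("a constant M field yields a constant surface with zero variance explained", {
  set.seed(20)
  mt <- make_m_table(t = runif(200, 3, 6), e = runif(200, 2.5, 3), M = rep(0.7, 200))
  fit <- fit_bias_model(mt)
  expect_equal(fit$variance_explained, 0)
  expect_equal(fit$fitted, rep(0.7, 200), tolerance = 1e-6)
  expect_equal(predict_bias(fit, c(3.5, 5.5), c(2.6, 2.9)), c(0.7, 0.7),
               tolerance = 1e-6)
})

test_that("a noise-free planted linear field is recovered almost exactly", {
  set.seed(21)
  t <- runif(500, 3, 6); e <- runif(500, 2.5, 5)
  M <- 0.5 * (t - mean(t))
  fit <- fit_bias_model(make_m_table(t, e, M))
  expect_lt(max(abs(fit$fitted - M)), 1e-3)
  expect_gte(fit$variance_explained, 0.99)
})

test_that("lambda = 0 equals the unpenalized normal-equations solution", {
  set.seed(22)
  n <- 400
  t <- runif(n, 3, 6); e <- runif(n, 2, 5)
  M <- sin(t) + 0.3 * e + rnorm(n, 0, 0.2)
  mt <- make_m_table(t, e, M)
  fit <- fit_bias_model(mt, k = 4, lambda = 0)
  # independent oracle: ordinary least squares on the same tensor basis
  B <- snucnorm:::.tensor_basis(
    snucnorm:::.bspline_eval(fit$knots_t, t),
    snucnorm:::.bspline_eval(fit$knots_e, e))
  theta <- qr.solve(crossprod(B), crossprod(B, M))
  expect_equal(unname(fit$coef), unname(drop(theta)), tolerance = 1e-6)
  expect_equal(fit$edf, ncol(B), tolerance = 1e-6)
})

test_that("effective degrees of freedom decrease monotonically in lambda", {
  set.seed(23)
  t <- runif(800, 3, 6); e <- runif(800, 2, 5)
  M <- 0.4 * t - 0.2 * e + rnorm(800, 0, 0.3)
  mt <- make_m_table(t, e, M)
  lams <- 10^seq(-4, 6, length.out = 11)
  edfs <- vapply(lams, function(l) fit_bias_model(mt, lambda = l)$edf, 0)
  expect_true(all(diff(edfs) < 1e-8))
  # at very large lambda the fit approaches the penalty null space
  # (bilinear surfaces): edf near 4
  expect_lt(edfs[length(edfs)], 4.5)
})

test_that("GCV fitting agrees with an independent GAM implementation", {
  set.seed(24)
  n <- 1500
  t <- runif(n, 3, 6)
  e <- t - rexp(n, 2) - 0.2
  f <- -0.8 * (t - 4.5) - 1.2 * (1 - 10^(e - t) - 0.8)
  M <- f + rnorm(n, 0, 0.5)
  mt <- make_m_table(t, e, M)
  fit <- fit_bias_model(mt)
  gam_fit <- mgcv::gam(M ~ s(t, e), family = gaussian(link = "identity"))
  expect_gt(stats::cor(fit$fitted, stats::fitted(gam_fit)), 0.98)
  # and both track the underlying field
  expect_gt(stats::cor(fit$fitted, f), 0.95)
})

test_that("degenerate covariates and oversized bases are rejected", {
  set.seed(25)
  mt_flat <- make_m_table(t = rep(4, 100), e = runif(100, 2, 3), M = rnorm(100))
  expect_error(fit_bias_model(mt_flat), "1-D")
  mt_small <- make_m_table(t = runif(60, 3, 6), e = runif(60, 2, 5), M = rnorm(60))
  expect_error(fit_bias_model(mt_small, k = 8), "exceeds")
  expect_error(fit_bias_model(mt_small[1:20, ]), "included genes")
})

test_that("prediction reproduces fitted values and clamps to the hull", {
  set.seed(26)
  t <- runif(300, 3, 6); e <- runif(300, 2, 5)
  M <- 0.3 * t - 0.1 * e + rnorm(300, 0, 0.1)
  mt <- make_m_table(t, e, M)
  fit <- fit_bias_model(mt)
  expect_equal(predict_bias(fit, t, e), fit$fitted, tolerance = 1e-10)
  # far outside the hull: clamped to the boundary evaluation
  expect_equal(predict_bias(fit, max(t) * 10, 3),
               predict_bias(fit, max(t), 3), tolerance = 1e-12)
  expect_equal(predict_bias(fit, 4, min(e) - 50),
               predict_bias(fit, 4, min(e)), tolerance = 1e-12)
  expect_error(predict_bias(fit, NaN, 3), "non-finite")
})

test_that("apply_correction is the expected multiplicative transform", {
  catal <- make_catalog(c(10000, 50000), c(2000, 3000))
  nucv <- matrix(c(10, 0, 4, 8), 2, 2,
                 dimnames = list(catal$gene_id, c("a", "b")))
  nuc <- expr_matrix(nucv, "FPM")
  # constant surface Mhat = 1: every value doubles, zeros stay zero
  set.seed(27)
  mt <- make_m_table(t = runif(100, 3.5, 5), e = runif(100, 3, 3.5), M = rep(1, 100))
  fit <- fit_bias_model(mt)
  corr <- apply_correction(nuc, fit, catal)
  expect_equal(corr$values, nucv * 2, tolerance = 1e-6)
  expect_equal(em_layer(corr), "correctedFPM")
  # null surface: identity
  mt0 <- make_m_table(t = runif(100, 3.5, 5), e = runif(100, 3, 3.5), M = rep(0, 100))
  corr0 <- apply_correction(nuc, fit_bias_model(mt0), catal)
  expect_equal(corr0$values, nucv, tolerance = 1e-6)
  expect_error(apply_correction(corr, fit, catal), "layer")
})

test_that("correction removes the planted surface from synthetic data", {
  cfg <- sim_config(n_genes = 3000, n_cells = 100, n_nuclei = 100, seed = 30,
                    divergent_fraction = 0)
  catal <- generate_catalog(cfg)
  sim <- generate_counts(catal, cfg)
  fpm_c <- counts_to_fpm(sim$cell); fpm_n <- counts_to_fpm(sim$nucleus)
  mt <- compute_m_values(fpm_c, fpm_n, catal)
  fit <- fit_bias_model(mt)
  corr <- apply_correction(fpm_n, fit, catal)
  mt2 <- compute_m_values(fpm_c, corr, catal)
  fit2 <- fit_bias_model(mt2)
  expect_lt(fit2$variance_explained, fit$variance_explained)
  expect_lt(fit2$variance_explained, 0.02)
})

test_that("planted divergence survives the correction", {
  cfg <- sim_config(n_genes = 3000, n_cells = 100, n_nuclei = 100, seed = 31,
                    divergent_fraction = 0.05, divergent_effect = 2)
  catal <- generate_catalog(cfg)
  sim <- generate_counts(catal, cfg)
  fpm_c <- counts_to_fpm(sim$cell); fpm_n <- counts_to_fpm(sim$nucleus)
  mt <- compute_m_values(fpm_c, fpm_n, catal)
  fit <- fit_bias_model(mt)
  corr <- apply_correction(fpm_n, fit, catal)
  mt2 <- compute_m_values(fpm_c, corr, catal)
  div <- sim$truth$gene_id[sim$truth$divergent]
  post_m <- mt2$M[match(div, mt2$gene_id)]
  # subtract each divergent gene's own non-structural scatter so the check
  # isolates what the correction did to the planted delta
  post_delta <- post_m - sim$truth$m_noise[match(div, sim$truth$gene_id)]
  expect_gte(mean(abs(post_delta)), 0.5 * cfg$divergent_effect)
})

test_that("pure-noise M fields report near-zero variance explained", {
  set.seed(32)
  n <- 5000
  t <- runif(n, 3, 6); e <- t - rexp(n, 2) - 0.1
  mt <- make_m_table(t, e, M = rnorm(n))
  fit <- fit_bias_model(mt)
  expect_lte(fit$variance_explained, 0.05)
  rep <- variance_explained_report(fit)
  expect_equal(rep$variance_explained, fit$variance_explained)
  expect_true(rep$edf >= 3 && rep$edf <= 25)
})

test_that("variance explained recovers the generative variance fraction", {
  ves <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 5000, seed = s, divergent_fraction = 0)
    catal <- generate_catalog(cfg)
    cfg <- calibrate_m_noise(catal, cfg, rho = 0.4)
    sim <- generate_counts(catal, cfg)
    mt <- compute_m_values(counts_to_fpm(sim$cell), counts_to_fpm(sim$nucleus), catal)
    fit_bias_model(mt)$variance_explained
  }, 0)
  expect_equal(mean(ves), 0.4, tolerance = 0.05)
})

test_that("bias fits refit identically and survive serialization", {
  set.seed(33)
  t <- runif(300, 3, 6); e <- runif(300, 2, 5)
  M <- 0.2 * t + rnorm(300, 0, 0.2)
  mt <- make_m_table(t, e, M)
  f1 <- fit_bias_model(mt); f2 <- fit_bias_model(mt)
  expect_identical(f1$coef, f2$coef)
  path <- tempfile(fileext = ".json")
  write_bias_fit(f1, path)
  back <- read_bias_fit(path)
  qt <- runif(20, 2.5, 6.5); qe <- runif(20, 1.5, 5.5)
  expect_equal(predict_bias(back, qt, qe), predict_bias(f1, qt, qe),
               tolerance = 1e-12)
})
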