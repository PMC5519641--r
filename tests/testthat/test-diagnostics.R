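make_log_pair <- function(cellv, nucv) {
  gid <- sprintf("g%d", seq_len(nrow(cellv)))
  dimnames(cellv) <- list(gid, sprintf("c%d", seq_len(ncol(cellv))))
  dimnames(nucv) <- list(gid, sprintf("n%d", seq_len(ncol(nucv))))
  list(cell = expr_matrix(cellv, "logFPM"),
       nuc = expr_matrix(nucv, "logFPM"))
}

test_that("identical groups produce no differentially detected genes", {
  set.seed(40)
  v <- matrix(rnorm(200, 5), 20, 10)
  p <- make_log_pair(v, v)
  res <- differential_detection(p$cell, p$nuc)
  expect_false(any(res$passes))
  expect_true(all(res$log_fold_change == 0))
})

test_that("a strongly shifted gene is detected and matches the Welch oracle", {
  set.seed(41)
  n <- 50
  cellv <- rbind(planted = rnorm(n, 7, 0.1), null = rnorm(n, 5, 0.1))
  nucv <- rbind(planted = rnorm(n, 5, 0.1), null = rnorm(n, 5, 0.1))
  p <- make_log_pair(cellv, nucv)
  res <- differential_detection(p$cell, p$nuc)
  planted <- res[res$gene_id == "g1", ]
  expect_true(planted$passes)
  expect_lt(planted$p_value, 1e-6)
  expect_equal(planted$direction, "up_in_cells")
  # oracle: stats::t.test Welch on the same vectors
  oracle <- stats::t.test(cellv["planted", ], nucv["planted", ])
  expect_equal(planted$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(planted$log_fold_change,
               mean(cellv["planted", ]) - mean(nucv["planted", ]))
})

test_that("the fold-change screen precedes testing", {
  set.seed(42)
  n <- 50
  # true shift 0.5 with tiny variance: p would be tiny, but the screen fails
  cellv <- rbind(g = rnorm(n, 5.5, 0.01))
  nucv <- rbind(g = rnorm(n, 5.0, 0.01))
  p <- make_log_pair(cellv, nucv)
  res <- differential_detection(p$cell, p$nuc)
  expect_false(res$passes)
  expect_true(is.na(res$p_value))  # never tested
  # with a lower threshold the same gene is tested and passes
  res2 <- differential_detection(p$cell, p$nuc, lfc_threshold = 0.25)
  expect_true(res2$passes)
  expect_lt(res2$p_value, 0.01)
})

test_that("tightening thresholds never enlarges the passing set", {
  set.seed(43)
  cellv <- matrix(rnorm(3000, 5, 1), 100, 30) +
    matrix(rep(rnorm(100, 0, 1.2), 30), 100, 30)
  nucv <- matrix(rnorm(3000, 5, 1), 100, 30)
  p <- make_log_pair(cellv, nucv)
  base <- differential_detection(p$cell, p$nuc, lfc_threshold = 0.5,
                                 p_threshold = 0.05)
  tighter_lfc <- differential_detection(p$cell, p$nuc, lfc_threshold = 1.0,
                                        p_threshold = 0.05)
  tighter_p <- differential_detection(p$cell, p$nuc, lfc_threshold = 0.5,
                                      p_threshold = 0.001)
  pass <- function(r) r$gene_id[r$passes]
  expect_true(all(pass(tighter_lfc) %in% pass(base)))
  expect_true(all(pass(tighter_p) %in% pass(base)))
})

test_that("top_gene_table applies a strict cutoff and orders by p", {
  res <- structure(data.frame(
    gene_id = c("a", "b", "c", "d"),
    log_fold_change = c(2, -2, 3, 1.5),
    p_value = c(0.5, 1e-30, 1e-20, NA),
    direction = c("up_in_cells", "up_in_nuclei", "up_in_cells", "up_in_cells"),
    passes = c(FALSE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE),
    class = c("diff_detection", "data.frame"))
  top <- top_gene_table(res)
  # boundary: exactly 1e-20 is excluded (strict inequality)
  expect_equal(top$gene_id, "b")
  expect_equal(nrow(top_gene_table(res, p_cut = 1)), 3L)
  expect_equal(top_gene_table(res, p_cut = 1)$gene_id, c("b", "c", "a"))
  all_half <- res; all_half$p_value <- 0.5
  expect_equal(nrow(top_gene_table(all_half)), 0L)
})

test_that("length_bias_test behaves at the null and under separation", {
  # identical length multisets: t statistic 0, p = 1
  catal <- make_catalog(rep(c(1000, 2000, 4000), 2), rep(500, 6),
                        ids = sprintf("G%d", 1:6))
  rep0 <- length_bias_test(c("G1", "G2", "G3"), c("G4", "G5", "G6"), catal)
  expect_equal(rep0$student_t_p, 1)
  # strong separation: 10 kb vs 100 kb with jitter, both tests reject hard
  set.seed(44)
  lens <- c(round(rnorm(100, 10000, 500)), round(rnorm(100, 100000, 5000)))
  catal2 <- make_catalog(lens, pmin(lens, 2000), ids = sprintf("G%d", 1:200))
  up <- sprintf("G%d", 1:100); down <- sprintf("G%d", 101:200)
  rep1 <- length_bias_test(up, down, catal2)
  expect_lt(rep1$student_t_p, 1e-10)
  expect_lt(rep1$wilcoxon_p, 1e-10)
  # exchanging the sets leaves both p values unchanged
  rep2 <- length_bias_test(down, up, catal2)
  expect_equal(rep2$student_t_p, rep1$student_t_p)
  expect_equal(rep2$wilcoxon_p, rep1$wilcoxon_p)
  # and matches direct stats calls on log10 lengths
  expect_equal(rep1$student_t_p,
               stats::t.test(log10(lens[1:100]), log10(lens[101:200]),
                             var.equal = TRUE)$p.value)
  expect_error(length_bias_test(up, c(up[1], down[1:5]), catal2), "overlap")
  expect_error(length_bias_test(up[1], down, catal2), "at least 2")
})

test_that("gene_type_composition counts detection at the exact threshold", {
  catal <- make_catalog(rep(1000, 4), rep(500, 4),
                        gene_type = c("protein_coding", "protein_coding",
                                      "lincRNA", "antisense"))
  v <- cbind(c1 = c(3, 4, 10, 0), c2 = c(4, 4, 4, 4))
  rownames(v) <- catal$gene_id
  m <- expr_matrix(v, "counts", source = c("cell", "nucleus"))
  comp <- gene_type_composition(m, catal)
  # count 3 is not detected; 4 is
  expect_equal(comp$per_cell$n_detected, c(2L, 4L))
  expect_equal(comp$per_cell$pct_protein_coding, c(50, 50))
  expect_equal(comp$per_cell$pct_lincRNA, c(50, 25))
  # percentages sum to 100 per cell
  pct_cols <- grep("^pct_", names(comp$per_cell))
  expect_equal(unname(rowSums(comp$per_cell[, pct_cols])), c(100, 100))
  # all protein_coding: composition is 100% that type
  catal_pc <- make_catalog(rep(1000, 4), rep(500, 4))
  comp_pc <- gene_type_composition(expr_matrix(v, "counts"), catal_pc)
  expect_equal(comp_pc$per_cell$pct_protein_coding, c(100, 100))
})

test_that("gene_type_composition matches a brute-force per-cell recount", {
  set.seed(45)
  catal <- generate_catalog(sim_config(n_genes = 300, seed = 45))
  v <- matrix(rpois(300 * 8, 3), 300, 8,
              dimnames = list(catal$gene_id, sprintf("c%d", 1:8)))
  m <- expr_matrix(v, "counts")
  comp <- gene_type_composition(m, catal, detect_min_count = 4)
  for (j in 1:8) {
    det <- v[, j] >= 4
    expect_equal(comp$per_cell$n_detected[j], sum(det))
    tt <- table(catal$gene_type[det])
    for (ty in names(tt))
      expect_equal(comp$per_cell[[paste0("pct_", ty)]][j],
                   unname(tt[ty]) / sum(det) * 100)
  }
})

test_that("before_after_report issues the strict bias_removed verdict", {
  catal <- make_catalog(c(rep(10000, 5), rep(60000, 5)), rep(2000, 10),
                        ids = sprintf("G%d", 1:10))
  res <- structure(data.frame(
    gene_id = catal$gene_id, log_fold_change = rep(c(2, -2), 5),
    p_value = 1e-5, direction = rep(c("up_in_cells", "up_in_nuclei"), 5),
    passes = TRUE, stringsAsFactors = FALSE),
    class = c("diff_detection", "data.frame"))
  b1 <- length_bias_test(sprintf("G%d", 1:5), sprintf("G%d", 6:10), catal,
                         stage = "before")
  b2 <- length_bias_test(sprintf("G%d", c(1, 3, 6, 8)),
                         sprintf("G%d", c(2, 4, 7, 9)), catal, stage = "after")
  rep <- before_after_report(res, res, b1, b2)
  expect_equal(rep$bias_removed, b2$student_t_p > 0.05 && b2$wilcoxon_p > 0.05)
  # alpha = 1: strict inequality can never hold
  rep_strict <- before_after_report(res, res, b1, b2, alpha = 1)
  expect_false(rep_strict$bias_removed)
  # mismatched gene universes are rejected
  res2 <- res[1:8, ]; class(res2) <- class(res)
  expect_error(before_after_report(res, res2, b1, b2), "universe")
})
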