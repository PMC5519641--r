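# snucnorm

Gene-length bias correction for single-nucleus RNA-seq.

## The problem

Nuclei are full of nascent, intron-containing transcripts. When single-nucleus
libraries are quantified over the whole genic span (intron-inclusive counting —
the only practical choice given their thin exonic coverage), long and
intron-rich genes soak up reads relative to matched whole-cell libraries.
Comparing nuclei to cells then shows a systematic structural bias: genes
"up in nuclei" are long, genes "up in cells" are short, and the effect is
easily mistaken for biology. `snucnorm` is for anyone comparing nuclear and
cellular expression profiles — method developers benchmarking nucleus-based
protocols, or analysts harmonising single-nucleus and single-cell atlases.

## The model

For each gene the package computes the log2 fold expression ratio between the
averaged whole-cell and nuclear profiles,

    M_g = log2( (mean FPM_cell,g + c) / (mean FPM_nuc,g + c) ),

and fits a generalized additive model with a two-dimensional smooth over
`t = log10(genic length)` and `e = log10(exonic length)`,

    M ~ s(t, e),   Gaussian errors, identity link,

implemented as a tensor-product penalized B-spline surface with
GCV-selected smoothing. Nuclear expression is corrected multiplicatively,
`FPM_corrected = FPM_nuc * 2^Mhat(t, e)`, so genes obeying the surface have an
expected post-correction log2 ratio of zero while genuine divergence from the
surface is preserved. A diagnostic battery (differential detection with a
fold-change screen and Welch t tests, Student/Wilcoxon gene-length tests on
the up/down sets before and after correction, ERCC spike-in dose-response
correlations, gene-type composition of detected genes) verifies that the bias
was removed. A fully deterministic simulator generates paired nucleus/cell
count matrices with a planted, recoverable bias surface for end-to-end
validation.

## Worked example

Simulate a 5000-gene, 100 cell + 100 nucleus experiment with the default
planted bias, fit the surface, correct, and test whether the length bias
survives:

```r
library(snucnorm)

cfg      <- sim_config(n_genes = 5000, n_cells = 100, n_nuclei = 100, seed = 1)
catalog  <- generate_catalog(cfg)
sim      <- generate_counts(catalog, cfg)
fpm_cell <- counts_to_fpm(sim$cell)
fpm_nuc  <- counts_to_fpm(sim$nucleus)

fit <- fit_bias_model(compute_m_values(fpm_cell, fpm_nuc, catalog))
fit
#> bias_fit: tensor-product P-spline s(t, e), 5 x 5 basis
#>   genes fitted: 4989 | lambda = 5.623e-05 (GCV) | edf = 16.35
#>   variance explained: 0.473

corrected <- apply_correction(fpm_nuc, fit, catalog)
pre  <- differential_detection(log1p_expr(fpm_cell), log1p_expr(fpm_nuc))
post <- differential_detection(log1p_expr(fpm_cell), log1p_expr(corrected))
sets <- function(r) list(up = r$gene_id[r$passes & r$direction == "up_in_cells"],
                         down = r$gene_id[r$passes & r$direction == "up_in_nuclei"])
s1 <- sets(pre); s2 <- sets(post)
before_after_report(pre, post,
  length_bias_test(s1$up, s1$down, catalog, stage = "before"),
  length_bias_test(s2$up, s2$down, catalog, stage = "after"))
#>    stage n_pass n_up_in_cells n_up_in_nuclei   student_t_p    wilcoxon_p
#> 1 before   1226           901            325 1.135779e-214 5.738413e-137
#> 2  after    499           312            187  8.138907e-01  9.797885e-01
#> bias_removed (both post p > 0.05): TRUE
```

Before correction the genes detected higher in nuclei are dramatically longer
than those higher in cells (Student t p ~ 1e-214). After correction both
length tests are non-significant while ~500 genes — those carrying
length-independent biological differences — still pass differential
detection: the structural bias is gone, the biology is not. The fitted
surface explains 47% of the M-variance under the default planted signal;
`variance_explained_report(fit)` returns the number with the effective
degrees of freedom.

The whole analysis can also be driven in one call (`run_pipeline(cfg)`),
which writes every stage output plus a digest manifest, or from a shell via
`inst/scripts/run_pipeline.R` with a YAML config.

On real data, start from `parse_gene_lengths("annotation.gtf")` for the
catalog, read your count matrices with `read_expr_matrix()`, and proceed the
same way from `counts_to_tpm()` / `filter_cells()` / `filter_genes()` onward.

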