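---
title: "Correcting gene-length bias between single-nucleus and single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gene-length bias between single-nucleus and single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-nucleus RNA-seq profiles the transcriptome of isolated nuclei, which
are dominated by nascent, intron-containing transcripts. When gene
expression is quantified over the whole genic span (intron-inclusive
counting, which is necessary for nuclei because their exonic coverage is
low), long and intron-rich genes accumulate disproportionately many reads
in nuclear libraries relative to matched whole-cell libraries. Comparisons
between nuclei and cells then show a systematic, gene-structure-driven
bias: genes better detected in nuclei tend to be long, genes better
detected in whole cells tend to be short. Left uncorrected, this bias
masquerades as differential expression.

`snucnorm` quantifies the bias, models it, removes it, and verifies the
removal.

## The model

For each gene \(g\) we form the log2 fold expression ratio between the
averaged whole-cell and nuclear profiles,

\[
M_g = \log_2 \frac{\overline{\mathrm{FPM}}^{cell}_g + c}
                   {\overline{\mathrm{FPM}}^{nuc}_g + c},
\]

with pseudocount \(c\) (see below), and regress it on the two structural
covariates \(t_g = \log_{10}(\text{genic length})\) and
\(e_g = \log_{10}(\text{exonic length})\) with a generalized additive
model with Gaussian errors and identity link,

\[
M \sim s(t, e),
\]

where \(s\) is a two-dimensional smooth: a tensor-product cubic B-spline
surface (default 5 basis functions per margin, 25 coefficients) with
second-order difference penalties on the coefficient grid and a single
smoothing parameter \(\lambda\) chosen by generalized cross-validation on
a fixed logarithmic grid (\(10^{-8}\)–\(10^6\)). Because the penalty null
space contains all bilinear surfaces, a purely linear length bias is never
shrunk, while wigglier structure is damped according to GCV. The fit is
deterministic: identical input reproduces identical coefficients.

Nuclear expression is then corrected multiplicatively in linear FPM space:

\[
\mathrm{FPM}^{corr}_{gc} = \mathrm{FPM}^{nuc}_{gc}\cdot 2^{\hat M(t_g, e_g)},
\]

so a gene that obeys the surface has an expected post-correction
cell/nucleus log2 ratio of zero, zeros stay zero, and genuine biological
divergence — deviation *from* the surface — is preserved. Outside the
training covariate hull the surface is clamped to the hull boundary; the
spline is never extrapolated.

The orientation convention is fixed throughout: positive \(M\) means
higher in whole cells.

## Quantification and filters

Counts are normalised three ways, each tagged on the matrix so consumers
can refuse the wrong layer:

* **TPM** — per-base rates (counts / gene length) rescaled to \(10^6\) per
  cell; genic (intron-inclusive) length by default, exon-union length as
  an option.
* **FPM** — counts rescaled to \(10^6\) per cell with no length
  normalisation; the scale on which M values and the correction operate.
* **ERCC TPM** — computed over spike-in rows alone, so spike QC is
  independent of the endogenous transcriptome.

The inclusion filters mirror standard practice for these data: cells need
at least 1000 genes at \(\log_2(\mathrm{TPM}+1) \ge 1\); genes must be
expressed (same definition) in at least 3 cells; a gene counts as
*detected* in a cell at count \(\ge 4\). "log" is log2 throughout, and the
base is recorded in every filter report; the thresholds are arguments with
these defaults. Cells are filtered before genes; the gene filter is
applied to the pooled kept cells of both populations so that cells and
nuclei retain a single shared gene universe for the comparison.

## The synthetic-data generator

The generator produces paired nucleus/cell count matrices in which the
expected log2 cell/nucleus ratio of gene \(g\) is

\[
M_g^{true} = f(t_g, e_g) + \delta_g + \eta_g .
\]

* \(f\) is the planted bias surface, by default
  \(a\,(t - t_0) + b\,(\mathrm{ifrac} - i_0)\) with \(a = -0.9\) per decade
  of genic length and \(b = -1.5\) per unit intronic fraction: long,
  intron-rich genes are relatively higher in nuclei, with an amplitude of
  roughly \(\pm 2\) log2 units across the simulated length range. The
  functional form is configurable; the truth table always stores pointwise
  values so downstream checks are form-agnostic.
* \(\delta_g\) is one-sided biological divergence (default +2 log2 units,
  higher in cells) planted in a random 5% of genes, emulating transcripts
  genuinely enriched in the cytosol.
* \(\eta_g \sim N(0, \sigma_\eta)\) is gene-level biological scatter
  unrelated to gene structure (default \(\sigma_\eta = 0.5\)). Without it
  every gene would sit exactly on the surface and the surface would
  explain all non-sampling variance, which real data never show.
  `calibrate_m_noise()` solves for \(\sigma_\eta\) so that the surface
  accounts for a chosen fraction \(\rho\) of total M-variance,
  using the empirical surface variance over the catalog and an analytic
  delta-method allowance for negative-binomial sampling noise.

Observation model: per-gene rates are log-normal (median 300, sdlog 1.5);
per-cell library sizes log-normal (sdlog 0.3); counts are negative
binomial with size 2; optional independent Bernoulli dropout. These
defaults emulate deep intron-inclusive SMART-seq libraries of a few
million assigned reads per cell over a 5000-gene transcriptome. Gene
structure is drawn from log-normal models (genic length median 20 kb,
sdlog 1.5; exonic fraction median 0.15), giving the long, intron-rich
population typical of a mammalian brain transcriptome, with a configurable
mix of gene types for composition summaries. ERCC spike-ins span five
orders of magnitude of input with per-cell capture efficiency and
multiplicative capture noise whose default (sdlog 1.7) puts the mean
per-cell log-log Pearson r near 0.86, the regime reported for real C1
libraries. Read-category tables (CDS exon / intron / UTRs) are Dirichlet
with intron-rich means for nuclei, apportioned so each cell's categories
sum exactly to its read total.

Everything is a deterministic function of the config seed.

What the generator does *not* emulate: UMIs, read-level effects (GC,
positional coverage), amplification batch structure, cell-type mixtures
(cluster labels are inputs, not outputs), or any dependence of biological
divergence on gene structure. Passing the recovery tests therefore shows
the estimator is sound under this generative family, not that every real
data set satisfies its assumptions.

## Numerical and design choices

* **Pseudocount \(c = 0.125\) FPM.** The pseudocount must be small
  relative to the expression of genes near the 1-FPM detection bound: a
  pseudocount comparable to the means shrinks M toward zero for weakly
  expressed genes, the surface then systematically underestimates the
  bias, and the under-correction leaves a residual length signal that a
  5000-gene test battery detects. At \(c = 1/8\) the attenuation is below
  1% for included genes while \(M\) remains defined for genes absent from
  one population.
* **Uniform fitting weights.** Precision-style weights derived from the
  observed means are deliberately not used: a gene's nuclear mean scales
  with its own deviation from the surface, so outcome-dependent weights
  select against deviating genes and measurably bias the fitted surface.
  User-supplied covariate-based weights are accepted.
* **Fitting set.** Genes with mean \(\ge 1\) FPM in either population are
  fitted; the correction itself is applied to every gene through the
  clamped surface.
* **Averaged-profile fitting, per-cell correction.** The surface is fitted
  to cluster-mean M values (stable, one point per gene) and applied to
  every cell of the nuclear matrix.
* **Tie-breaks and degenerate inputs.** Constant M gives a constant
  surface with variance explained 0; degenerate covariates (all \(t\)
  equal) are an error recommending a 1-D model; an all-zero cell stays
  all-zero through every normalisation; both-groups-constant length tests
  return p = 1 (equal constants) or 0 (distinct constants) rather than
  erroring.
* **Test choices.** Differential detection uses a Welch t test on
  log2(expr+1) with a fold-change screen (|lfc| > 1) applied *before*
  testing, and a raw p < 0.01 threshold with no multiplicity correction —
  matching the conventional single-cell marker workflow this mirrors. The
  gene-length comparison between up/down sets uses an equal-variance
  Student t plus a Wilcoxon rank-sum on log10 genic length; with strongly
  separated sets the log/raw choice is immaterial, and it is recorded.
* **Interval semantics.** Exonic length is the per-base union of exon
  intervals pooled over all transcripts (1-based inclusive; touching
  intervals merge). The union choice matches intron-inclusive whole-gene
  counting; a longest-transcript convention would understate exonic
  length for genes with many alternative exons.
* **Orchestration.** The pipeline driver and config validator are plain R
  functions (`run_pipeline()`, `validate_config()`); a thin Rscript
  wrapper ships in `inst/scripts/` for shell use. Stage outputs are TSV
  and JSON, and the run manifest records config, seed, timings and file
  digests so deterministic stages can be verified byte-for-byte.

## Problem sizes used in validation

The shipped checks run the full pipeline at 5000 genes with 100 cells +
100 nuclei (ten seeds) for the bias-removal property, 500 + 500 cells for
surface recovery, and 50 + 50 cells for detection power — sizes at which
every property is stable while the whole battery completes in about a
minute.

## Known limitations

* The correction operates in linear FPM space on a per-gene multiplicative
  scale; at very shallow sequencing depth (a few thousand counts per
  cell), mean-of-log versus log-of-mean discrepancies of discrete counts
  leave a residual length signal that no means-based surface can remove.
  The method targets deep full-length libraries.
* A single surface is fitted per matched population pair; cell-type
  specific bias surfaces are out of scope.
* No uncertainty intervals are attached to \(\hat M\); the diagnostic
  battery, not a standard error, is the evidence that the correction
  worked.
* Divergence that is itself correlated with gene length is partially
  absorbed into the surface; the divergence-preservation guarantee assumes
  the divergent fraction is small (\(\le 5\%\)) and structure-independent.
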