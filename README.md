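# txmodes

Tools for asking a simple question of a whole transcriptome: **what shape is
the distribution of gene expression levels?** Metazoan RNA-seq studies have
described a bimodal log-expression distribution (a low-expression and a
high-expression peak); older SAGE/microarray work found power laws following
Zipf's law. `txmodes` implements the analysis pipeline needed to test both
claims on any RNA-seq dataset, from alignments to verdict, and a
synthetic-data generator that makes every stage testable against known
ground truth at desk scale.

The pipeline has three stages:

1. **Quantification.** From SAM alignments against per-locus reference
   sequences (annotated mRNAs or CDSs), only reads mapped *in their entire
   length to a single locus tag* are kept. Every base of a retained read is
   counted toward its locus ("coverage"), then normalized by locus length
   and the library's total counted bases,

   `norm(g) = raw_bases(g) / (length(g) · total_bases) · c`,  `c = 1e9`,

   and log2-transformed. Zero-coverage loci are excluded. RPKM is provided
   as an alternative measure for robustness checks.

2. **Mixture decomposition.** The log2 expression vector `x_1..x_n` is
   modeled as a finite mixture of univariate normals,

   `f(x) = Σ_k w_k N(x; μ_k, σ_k²)`, `Σ_k w_k = 1`,

   fitted by EM for each component count K (default 1..9) and variance
   family (E: equal σ², V: free σ²). The number of components and the family
   are selected by BIC (`2·loglik − p·ln n`, maximized). Each fitted
   component is a **peak**; a component with mixing proportion ≥ 15% of the
   clustered genes is a **main peak**. One main peak = unimodal, two =
   bimodal, three or more = multimodal.

3. **Zipf's-law test.** Genes are ranked by decreasing expression and log2
   expression is regressed on log2 rank by ordinary least squares. Under
   Zipf's law the plot is linear with gradient −1 (gradient −s for a general
   power law `C·r^(−s)`). Linearity is judged numerically: R² ≥ 0.98 and
   |quadratic curvature| ≤ 0.01 on the central 90% of ranks, with the
   full-range verdict reported alongside.

## Worked example

```r
library(txmodes)

# a synthetic transcriptome: 10,000 genes from a 3-component mixture
sim <- simulate_mixture(mixture_spec(
  weights = c(0.2, 0.5, 0.3), means = c(-4, 0, 4), variances = c(1, 1, 1),
  n_genes = 10000, seed = 42))

best <- select_model(sim$values)   # EM over K = 1..9, families E and V
print(best)
#> 3-component normal mixture (family E)
#>   n = 10000, loglik = -23686.1975, BIC = -47427.6570, converged in 8 iterations
#>   weight    mean variance
#> 1 0.2003 -3.9983   1.0189
#> 2 0.4983 -0.0022   1.0189
#> 3 0.3014  3.9636   1.0189

summarize_peaks(best, main_threshold = 0.15)
#> 3 peak(s), 3 main peak(s) at threshold 15% -> multimodal
```

BIC recovered the generating structure: K = 3, the equal-variance family
(the truth), weights within 0.003 of 0.2/0.5/0.3 and means within 0.04 of
−4/0/4. All three components hold ≥ 15% of genes, so the distribution is
classified multimodal. The same data fail the Zipf test, as mixture-shaped
data should:

```r
assess_linearity(fit_zipf(rank_expression(sim$values)))
#> Zipf rank regression: gradient -1.7895, intercept 21.5908, R^2 0.7534
#>   (n = 10000, quadratic coefficient -0.2985)
#>   Zipf-consistent (central window): FALSE; full range: FALSE
```

Quantification from alignment files works the same way at any scale; here on
the built-in 6-read fixture (3 clean reads retained, 2 multi-locus and 1
clipped read discarded):

```r
fx <- generate_sam_fixture(default_sam_fixture_spec())
quantify_sam(fx$sam, fx$annotation)$table
#>   locus_tag raw_bases length    norm log2_norm
#> 1      locA       100    300 2380952  21.18311
#> 2      locB        40    200 1428571  20.44614
#> 3      locC         0    150       0        NA
```

File-based entry points (`run_quantify`, `run_fit`, `run_zipf`,
`run_simulate`, `run_report`) write TSV/JSON outputs plus a run manifest;
a thin command-line dispatcher ships at `inst/cli/txmodes.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","txmodes.R",package="txmodes"))')" \
  simulate --scenario yeast_like --out sim_out --seed 1
```

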