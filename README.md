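# phasesig

Discovery of multi-phase gene-expression signatures from bulk blood
transcriptomes.

After an acute myocardial infarction the blood transcriptome moves through
distinct states — the acute event (D0), thirty days post-infarction (D30),
one year post-infarction (Y1) — and a compact gene set that separates those
phases is both a candidate staging biomarker and a handle on the biology of
recovery. `phasesig` implements the full discovery pipeline for such
signatures from a gene-level log-expression matrix with one phase label per
sample, for transcriptomics researchers who want the method reproducible,
parameterized and testable rather than buried in one-off scripts.

## The method

1. **Monte Carlo feature selection (MCFS).** Draw *s* random subsets of *m*
   genes, grow *t* information-gain decision trees per subset (each on a
   stratified 2/3 train split), and score every gene by its relative
   importance

   RI<sub>g</sub> = Σ<sub>τ=1..st</sub> (wAcc<sub>τ</sub>)<sup>u</sup>
   Σ<sub>n<sub>g</sub>(τ)</sub> IG(n<sub>g</sub>(τ)) ·
   (no. in n<sub>g</sub>(τ) / no. in τ)<sup>v</sup>

   summing information gain over the nodes of tree τ that split on *g*,
   damped by the node-size fraction (exponent *v*) and the tree's
   class-balanced held-out accuracy (exponent *u*; defaults u = v = 1,
   s = 100, t = 5).
2. **Incremental feature selection (IFS).** Evaluate the nested top-*N*
   prefixes of the ranking with leave-one-out cross-validated SVMs (RBF
   kernel, e1071 defaults, fold-internal standardization) and select the
   smallest *N* whose accuracy is within 0.005 of the grid maximum — the
   "small signature on the accuracy plateau" rule made explicit.
3. **Characterization.** Hierarchical clustering of signature genes and
   samples (correlation distance, average linkage, z-scored rows) with
   phase association per gene, and upper-tail hypergeometric
   over-representation against GMT gene-set collections with BH correction.

A synthetic three-phase generator with planted signatures
(`generate_synthetic()`) makes every stage testable end to end, including
parameter recovery, without downloading any cohort.

## Worked example

```r
library(phasesig)

sim <- generate_synthetic(synthetic_spec(
  n_genes = 200, n_samples_per_phase = c(20, 20, 15),
  n_informative = 6, effect_size = 2, seed = 7))
sim$expr
#> expr_matrix: 200 features x 55 samples
#> phases: D0=20, D30=20, Y1=15

ranking <- mcfs_rank(sim$expr, mcfs_params(s = 60, t = 3, seed = 7))
head(as.data.frame(ranking), 3)
#>   rank feature_id       ri
#> 1    1      g0127 6.319604
#> 2    2      g0006 5.097326
#> 3    3      g0168 3.205349
sort(match(sim$truth$gene, ranking$feature_id))
#> [1]  1  2  3  5  6 14

curve <- ifs_run(ranking, sim$expr, grid_max = 20)
curve
#> ifs_curve: 20 grid points, selected 6 features (LOOCV accuracy 0.891)
curve$confusion
#>       predicted
#> actual D0 D30 Y1
#>    D0  17   2  1
#>    D30  1  18  1
#>    Y1   1   0 14
```

The six planted genes rank 1, 2, 3, 5, 6 and 14 of 200; the plateau rule
stops at a 6-gene signature containing five of them, and its leave-one-out
confusion matrix shows 49/55 samples assigned to the correct phase
(accuracy 0.891). On real cohorts the same calls apply after
`read_expression()` and, for probe-level arrays,
`preprocess()` (probe-to-gene averaging followed by quantile
normalization).

The `analysis/` directory holds the same pipeline as a numbered workflow
(`01_simulate.R` ... `06_enrichment.R`) writing its tables under `results/`;
run the scripts in order from the repository root.

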