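---
title: "Phase-signature discovery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-signature discovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

After an acute myocardial infarction, the blood transcriptome keeps evolving:
the expression state at the acute event (D0), thirty days later (D30) and one
year later (Y1) are distinct, and a compact gene signature separating the
three phases is both a candidate staging biomarker and a window on the
biology of recovery. `phasesig` implements the discovery pipeline for such
signatures from a gene-level log-expression matrix with one phase label per
sample: rank all genes by Monte Carlo feature selection (MCFS), walk nested
top-*N* prefixes of the ranking with leave-one-out cross-validated SVMs
(incremental feature selection, IFS), pick the smallest prefix on the
accuracy plateau, then characterize the signature by clustering and gene-set
over-representation.

Everything below states what the package computes and why each default is
what it is. No empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Preprocessing

Array data arrives probe-level; `collapse_probes()` averages the probes of a
gene arithmetically on the stored log scale — "averaging" is conventionally
done on the scale the matrix is stored in, and all downstream steps are
scale-free given a monotone transform of ranks. `quantile_normalize()`
forces every sample onto the common per-rank-mean reference; ties within a
sample receive the mean of the reference values at their tied ranks, the
usual microarray convention, which makes the operation exactly idempotent.
The pipeline default is collapse-then-normalize (`preprocess()`), so the
normalized distribution is the one downstream steps actually see; the
opposite order is available because both conventions occur in practice.
Missing values are a hard error: imputation is a modelling decision that
should not happen silently inside plumbing.

## Monte Carlo feature selection

MCFS scores each gene by how much it contributes to an ensemble of decision
trees grown on random feature subspaces. With $d$ genes, $s$ subsets of $m$
genes are drawn uniformly without replacement and $t$ trees are grown per
subset, each on an independent stratified train/test split of the samples.
The relative importance of gene $g$ is

$$
\mathrm{RI}_g \;=\; \sum_{\tau=1}^{s\,t} (\mathrm{wAcc}_\tau)^u
\sum_{n_g(\tau)} \mathrm{IG}\!\left(n_g(\tau)\right)
\left(\frac{\mathrm{no.\,in}\ n_g(\tau)}{\mathrm{no.\,in}\ \tau}\right)^{\!v}
$$

summing over the nodes $n_g(\tau)$ of tree $\tau$ that split on $g$:
information gain of the split, damped by the fraction of the tree's training
samples reaching the node (exponent $v$) and by the tree's held-out accuracy
(exponent $u$).

Design choices the formula leaves open:

* **Tree algorithm.** Binary CART with the information-gain criterion,
  candidate thresholds at midpoints between consecutive distinct sorted
  values, growth to purity (`min_samples_split = 2`, unlimited depth).
  Information gain is the quantity the importance formula consumes, so it is
  also the split criterion. Ties between equally good splits go to the
  first feature in subset order, then the smallest threshold —
  deterministic given the seed.
* **wAcc.** Defined as macro-averaged per-class recall on the held-out third
  of the samples (`train_fraction = 2/3`, stratified by phase). A
  class-balanced definition keeps trees honest under the unbalanced cohort
  (65/64/37); if a phase is absent from a tree's held-out set, the average
  runs over the phases present.
* **Defaults.** $u = v = 1$ (the conventional regularization exponents);
  $s = 100$, $t = 5$ (500 trees — enough for ranks of genuinely informative
  genes to stabilize at the problem sizes below, small enough for desk-scale
  runs); $m = \max(\lceil 0.05\,d\rceil, \lceil\sqrt d\rceil)$, the usual
  random-subspace scale between $\sqrt d$ and a small fraction of $d$. All
  are arguments of `mcfs_params()`. Note that with $s\,t$ trees each gene is
  drawn with probability $1-(1-m/d)^{s}$; at the defaults on $d = 500$ about
  0.6% of genes are never drawn and score exactly 0 — raise $s$ if that
  matters.
* **Reproducibility and additivity.** Every subset's random stream derives
  from `(seed, subset index)`, so runs are bit-reproducible, and the subset
  budget can be split across calls (`subset_offset`) with the per-gene RI
  summing exactly to the single-run value — convenient for incremental
  accumulation and verified to 1e-9 in the tests.

## Incremental feature selection

`ifs_run()` evaluates the nested prefixes (top-1, top-2, ..., top-$N$) of
the ranking by leave-one-out cross-validation: train on all samples but one,
predict the one, accumulate a confusion matrix (rows actual, columns
predicted). The default classifier mirrors the standard `e1071::svm`
configuration: C-classification, RBF kernel, $C = 1$,
$\gamma = 1/\text{n features}$, one-vs-one multiclass, features standardized
with training-fold statistics only (no fold leakage; whether to standardize
at all is a choice the data cannot make for you — it is exposed via
`svm_classifier(scale =)`). The classifier is pluggable; a deterministic
1-NN spec exists mainly so tests can trace folds by hand.

The "smallest signature on the plateau" rule is formalized by
`select_optimal()`: the smallest evaluated $N$ whose accuracy is within
`epsilon = 0.005` (half a percentage point) of the grid maximum. A visual
plateau judgement is irreproducible; half a point is below the resolution of
LOOCV on cohorts of a few hundred samples, so the rule trades essentially no
accuracy for a much smaller signature.

Two statistical properties of this stage are worth knowing and are measured
by the test suite rather than assumed:

* **LOOCV pessimism.** Under a permuted-label null the held-out sample's
  class is always slightly underrepresented in its training fold, so LOOCV
  accuracy sits *below* chance — severely so for small cohorts (mean ~0.10
  at 10 samples/class for three classes, ~0.26 at 30/class). Calibration
  checks therefore use cohorts of 30+ samples per class.
* **Selection bias of rank-then-validate.** The ranking is computed on all
  samples, including each LOOCV test sample. On label-permuted data,
  re-ranking on the permuted labels and then cross-validating the top genes
  yields maximum grid accuracies of ~0.45–0.62 against a chance rate of
  1/3 — far outside binomial noise — at every cohort size we measured, up to
  the full 165-sample design. This is the classic out-of-loop
  feature-selection bias; it afflicts any pipeline that ranks before
  cross-validating, including this one. The package's null-calibration test
  fixes the ranking before permuting the evaluated labels (which isolates
  the LOOCV machinery, and is calibrated); the absolute LOOCV accuracy of a
  discovered signature should be confirmed on independent data before being
  quoted.

## Clustering and phase association

`cluster_report()` follows the standard expression-heatmap conventions:
genes z-scored across samples, correlation distance ($1 - r$), average
linkage, tree cut at $k = 3$ (one cluster per phase). Constant genes get a
zero z-score row and are treated as uncorrelated. The metric and linkage are
arguments because no single choice is canonical. Cluster indices are
renumbered by first appearance so memberships do not depend on input order.
`phase_association()` labels each gene with its highest-mean phase
(deterministic first-phase tie-break, flagged) and classifies the trend of
the per-phase means as increasing, decreasing or other. Exports are
data-only (TSVs in dendrogram order); rendering is left to the example
script, keeping the package free of graphics dependencies.

## Enrichment

`enrich()` performs the upper-tail (inclusive, $P(X \ge k)$) hypergeometric
over-representation test per term, evaluated through the log-space
distribution function, with Benjamini–Hochberg correction across the terms
of the collection being tested — collections (GO BP/CC/MF, KEGG) should be
tested separately, matching how such results are conventionally reported.
The default universe is the genes of the expression matrix, not of the
collection: the query was drawn from measured genes, so the background must
be too. Collection- and explicit-universe modes exist for when the matrix is
unavailable. Terms with zero overlap carry no evidence and are hidden unless
requested.

## The synthetic generator

`generate_synthetic()` is first-class, tested code: it is what makes every
stage of the pipeline testable without any external download. It emulates a
quantile-normalized log-intensity matrix for the three-phase cohort design
(defaults: 65/64/37 samples, 500 genes, 10 informative at 2 noise-sd,
baseline 8, unit noise): background genes i.i.d. Gaussian per value,
informative genes shifted per phase by `monotone_up` $(0, \delta/2,
\delta)$, `monotone_down` $(\delta, \delta/2, 0)$ or `high_<phase>`
($\delta$ in one phase), $\delta$ = `effect_size * noise_sd`. Gaussian noise
on the log scale is the right first approximation for quantile-normalized
array data; a $t$-noise option and an equicorrelated-block option (shared
latent factor per pattern block) exist for robustness checks and for
emulating co-expression, both off by default.

What it does **not** emulate: probe-level effects, batch structure,
mean–variance coupling, heavy co-expression among background genes, or
class-dependent covariance. Passing the recovery tests therefore shows the
pipeline's machinery is correct and calibrated under the stated model — not
that a real cohort would yield a signature of any particular size or
accuracy.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise the
statistics meaningfully: formula-level oracles on cohorts of ≤ 30 samples;
null calibration on 3 × 20 samples × 150 genes with a 20-point grid;
parameter recovery at the full 65/64/37 design with 500 genes, 10 planted
genes at 2 noise-sd, the default 500-tree ranking budget and a selection
grid to 50, repeated over 5 seeds (the headline check: mean planted-gene
recovery ≥ 0.7 and mean LOOCV accuracy ≥ 0.85). Tolerances: exact identities
(quantile-normalization fixed points, sorted-column equality) are asserted
exactly; formula equivalences to 1e-9; enumeration oracles to 1e-12;
stochastic claims via 3-standard-error binomial bands at fixed seeds.

Known limitations: RI values depend on the tree-growth controls and are
comparable only within one parameterization; the plateau rule inherits the
granularity of the evaluation grid; hierarchical clustering with correlation
distance is undefined for constant items (handled by convention, above); and
the discovered signature's accuracy estimate is optimistic for the reasons
given in the selection-bias note.
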