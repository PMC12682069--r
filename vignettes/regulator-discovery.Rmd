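---
title: "Discovering regulators of a target gene and layering them into a network"
author: "grnlayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering regulators of a target gene and layering them into a network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlayers)
```

## The problem

Plants accumulate terpenoid secondary metabolites under environmental
stress, and the terpene synthase (TPS) genes that produce them sit at the
bottom of transcription-factor (TF) cascades. Given a gene-by-sample RNA-seq
counts matrix, a list of annotated TFs and one target gene of interest
(for instance a caryophyllene synthase whose expression acts as a
quantitative phenotype), two questions recur:

1. **Which TFs are credible regulators of the target?** Answered here by a
   consensus of three screens — a co-expression/gene-significance screen, a
   Boruta shadow-feature screen over random-forest regression, and SVM
   recursive feature elimination — intersected to suppress false positives.
2. **How are the regulators organized above a set of stress-responsive
   genes?** Answered by a bottom-up Gaussian-graphical-model construction:
   gene pairs that are strongly co-expressed (Pearson r at least `cc_min`)
   and whose association collapses when conditioning on a TF
   (|partial correlation| below `pcc_max`) are attributed to that TF; TFs so
   placed become the next "bottom" and the step repeats, yielding a layered
   TF-to-TF-to-gene hierarchy.

Because real studies of this kind hinge on external sequencing archives, the
package ships a synthetic-data module that plants a known three-layer
regulatory cascade, known differential expression and a known phenotype
driver set, so that every stage can be scored against ground truth.

## The model behind the simulator

`simulation_config()` describes a linear-Gaussian structural-equation system
on the log2 scale. Top-layer TFs are standard normal across samples; every
other cascade node is a coefficient-weighted sum of its parents plus
`Normal(0, noise_sd)`, then variance-standardized. Standardization leaves
every correlation untouched (correlations are scale-invariant) but keeps
latent log2 amplitudes realistic at any cascade depth — without it,
variance accumulates down the layers and single genes swing over orders of
magnitude, dominating library totals in small panels. Expressed noise TFs
have no parents, so their structural part is pure residual,
`Normal(0, noise_sd)`. Coefficient magnitudes are uniform on
`coeff_range`.
A per-gene baseline (uniform on `baseline_log2_range`, default 3–8 log2
units, i.e. moderately to highly expressed genes) shifts the latent values
into a realistic abundance range. Planted differential expression adds, on
the latent scale, a shift that ramps linearly across the ordered condition
groups from 0 to the planted log2 fold change, so the true log2FC between
the first and last group is exact by construction. Counts are Poisson with
mean proportional to `2^latent * length[kb] * depth[millions]`; a
negative-binomial option (`dispersion`) exists but is off by default because
the downstream inference operates on FPKM/log values, where count
dispersion is not load-bearing.

Defaults mirror the scale of the motivating study design: 87 samples in
three light-intensity groups, 2079 annotated TFs of which 400 are silent
(so 1679 survive the zero-expression filter), a planted hierarchy of
14 top TFs, 134 mid TFs and 131 pathway genes, and a target gene driven by
five mid-layer TFs. One global seed drives a fixed per-stage seed sequence,
so changing the sample count never perturbs the network draw.

What the simulator deliberately does **not** emulate: read-level artifacts
(no FASTQ, no mapping bias), batch effects, overdispersion beyond the
optional NB switch, and nonlinear or combinatorial regulation. Passing the
recovery tests therefore demonstrates correctness of the inference
machinery under the model's own assumptions, not performance on arbitrary
real data.

## Normalization and the DEG screen

`fpkm()` implements fragments per kilobase per million mapped fragments
with the per-sample column total standing in for the mapped-fragment total
(alignment totals are not available downstream of quantification); columns
are exactly invariant under per-sample count scaling. `drop_unexpressed()`
removes rows whose total is exactly zero — the same rule that reduces a
2079-TF panel to 1679 expressed TFs. All correlation stages run on
`log2(FPKM + 1)`; the pseudocount (default 1) is configurable.

The differential-expression screen is intentionally simple: a two-sided
Welch t-test on `log2(FPKM + 1)` with the screening rule *P* < 0.05 and
|log2FC| > 1, and union semantics across the pairwise group comparisons.
A negative-binomial count model is *not* re-implemented; what downstream
stages consume is the threshold rule, and the test sits behind a single
interface (`de_test()`) so another test can be substituted. Raw p-values
are used by default, matching the screening rule; Benjamini–Hochberg
correction is available via `adjust = TRUE`.

A note on small matrices: FPKM divides by the per-sample total, so in a
matrix with only a handful of genes the shared signal itself dominates the
totals and is cancelled out (compositional closure). Realistic inputs have
thousands of ballast genes and do not exhibit this; the package's test
fixtures include a few hundred unrelated noise TFs for the same reason.

## The co-expression stage

The module stage is a compact, unsigned (|r|-based) implementation:

- **Soft power.** For candidate powers, adjacency `|r|^beta` and
  connectivity `k_i = sum_j a_ij`; the scale-free fit index is the R² of
  `log10 p(k)` against `log10 k` over 15 equal-width bins (empty bins
  dropped). The chosen power is the smallest candidate reaching
  `target_fit` (default 0.8), otherwise the argmax; a degenerate scan with
  constant connectivity scores 0.
- **Topological overlap.** `TOM_ij = (sum_u a_iu a_uj + a_ij) /
  (min(k_i,k_j) + 1 - a_ij)`, unit diagonal.
- **Modules.** Average-linkage clustering on `1 - TOM` with a *static* cut
  at `cut_fraction` (default 0.99) of the maximal merge height, then
  pruning of clusters below `min_size` (default 30) to an `unassigned`
  label. Dynamic tree cutting is not re-implemented: the module stage's
  downstream role is only TF co-membership with the target, which a static
  cut serves, and the cut is pluggable.
- **Eigengenes and screening.** The module eigengene is the first principal
  component of the per-gene z-scored submatrix, sign-fixed against the
  module mean profile. Gene significance is `GS = |cor(gene, trait)|` with
  the exact t-transform p-value; the screen keeps `GS >= 0.65` at
  `P < 1e-5`. (A stricter `P < 1e-10` variant appears in some published
  uses of the rule; both are plain parameters here.) The trait is the
  target gene's own expression vector.

## Consensus feature selection

**Boruta.** Each iteration appends permuted shadow copies of the active
features, fits a random forest, and scores a hit for features whose
importance exceeds the maximum shadow importance; cumulative hit counts are
tested two-sided against Binomial(i, 0.5) at alpha = 0.01 with Bonferroni
correction across features, for up to 300 iterations, with rejected
features leaving the model. Two design details matter for error control
and were chosen by explicit null/recovery calibration on planted panels:

- *Importance.* The default is raw (unscaled) out-of-bag permutation
  importance. Impurity importance rewards features whose apparent signal
  is in-sample chance correlation (they genuinely improve training-set
  splits), inflating false confirmations, while the z-scored permutation
  variant divides by per-tree variability and thereby inflates rarely
  used features; the raw measure separates weak true predictors from the
  shadow maximum best. Impurity remains available via
  `boruta_config(importance = "impurity")`.
- *Shadow floor.* Shadows are permuted copies of the active features, but
  the pool never falls below `shadow_floor` (default 40) columns: if the
  pool shrank freely as features were rejected, borderline features late
  in the run would face the maximum of only a handful of null draws — an
  ever-lower bar that persistent in-sample chance correlation clears more
  often than not, producing false confirmations.

**RF consensus.** Ten 75/25 train/test splits; on each training set the
forest's features-per-split parameter is tuned by repeated 10-fold
cross-validation minimizing MSE, Boruta runs, a forest on the confirmed
features is scored by held-out R², and the reported set is the intersection
of confirmed sets across splits. Tentative features are excluded by default
(`include_tentative` flips this).

**SVM-RFE.** Features are z-scored; C and gamma are tuned on the full set
by 10-fold cross-validated RMSE over the grid C in {0.1, 1}, gamma in
{0.1, 1}. Gamma is expressed *relative to the `1/p` library default*: an
absolute width of 0.1 over hundreds of standardized features makes every
kernel entry `exp(-0.1 * ||x - x'||^2)` effectively zero and the model
constant, so the relative scale is what keeps the stated grid meaningful
across feature-set sizes (`gamma_scale = FALSE` restores absolute values).
The RBF kernel has no weight vector, so the per-round elimination criterion
is permutation degradation of held-out RMSE (squared weights are used for
the linear kernel); each round removes the worst 10% of the remainder (at
least one), ranks are assigned in elimination order, fold-wise ranks are
averaged and ties break lexicographically. Candidate subset sizes run from
50 upward in steps of 100 plus the full set; the cross-validated-RMSE
argmin (ties to the smaller size) is reported, and the top 30 features by
average rank form the key-regulator set.

**Consensus.** The intersection of the GS set (restricted to TFs
co-assigned to the target's module when it has one), the RF consensus set
and the RFE set, annotated with each member's supporting statistics.

## Bottom-up layered network construction

The first-order partial correlation
`r_xy|z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` measures
what remains of a pair's association after removing a TF's linear effect.
`build_network()` iterates: co-expressed pairs in the current layer
(signed `r >= cc_min`, default 0.8), candidate TFs whose conditioning
collapses a pair (`|r_xy|z| < pcc_max`, default 0.3) gain edges to both
members, placed TFs form the next layer and leave the pool, up to
`max_layers` (default 3: primary TFs, secondary TFs, functional genes).
Duplicate edges keep the record with the smallest |pcc| — the strongest
conditioning evidence. Strict layering makes the result acyclic by
construction, and TFs that are themselves bottom-layer members stay in
layer 0 and never regulate their own layer.

**Proximal-regulator pruning.** Conditioning on one TF at a time has a
known blind spot: any near-perfect proxy of a true regulator — in a tight
cascade, its own upstream TF, or a co-regulated sibling — also collapses
the pair, so the naive rule attributes edges to grandparents and
co-parents. The package therefore applies a second first-order pass by
default: an edge `z -> x` is dropped when another candidate `z2` of the
same target screens `z` off from `x` (`|r(x,z|z2)| < pcc_max`) while `z2`'s
own association survives conditioning on `z`. Mutually collapsing
candidates are both kept, since the data cannot orient them. On planted
cascades this raises edge precision from roughly one third to above 0.9
without hurting recall; `prune_proxies = FALSE` restores the literal
keep-all behaviour. No full inverse-covariance (graphical-lasso) estimation
is attempted.

Open representational choices were resolved as follows: pair screening uses
*signed* r (positive co-expression), with an absolute-value mode behind a
flag, while the regulator criterion uses |pcc|, whose sign carries no
orientation information; when several TFs legitimately explain the same
pair, all surviving TFs are kept; and both pair members receive the edge.

## Numerical choices and degenerate inputs

- Correlation p-values use the exact t-transform, not permutations.
- Zero-variance genes: `r = 0` (flagged) in correlation matrices, `GS = 0`
  with `p = 1` in the GS table, dropped before eigengene standardization,
  dropped with a warning before Boruta/RFE.
- `|r| = 1` conditioning variables raise a degeneracy error in
  `partial_corr()`; inside `infer_layer_regulators()` the offending
  (pair, TF) combination is skipped and counted, not fatal.
- Welch tests on rows where both groups are constant report p = 1 when the
  means agree and p = 0 otherwise.
- Ties: module labels order by decreasing size; RFE rank ties break by
  feature identifier; equal-RMSE subsets resolve to the smaller size;
  equal soft-power fits resolve to the smaller power.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately modest sizes chosen to
exercise every code path at realistic signal-to-noise: oracle equivalence
on 1000 trivariate draws (n = 200) and 50 random adjacencies up to 40x40;
cascade recovery on ten simulations of a 1-top/2-mid/4-gene network with
200 ballast noise TFs at n = 300; feature-selection recovery on ten
datasets of 10 planted predictors among 90 noise features at n = 200
(forests of 200 trees there; the default is 500); DEG calibration on
2000-gene null and planted panels; and an end-to-end determinism check on a
45-sample three-group simulation. The full-scale defaults (87 samples,
1679 expressed TFs) run the same code unchanged.

## Worked example

```{r example, eval = FALSE}
library(grnlayers)

cfg <- run_config(
  simulation = simulation_config(n_samples = 60, n_top_tfs = 2,
                                 n_mid_tfs = 6, n_genes = 10,
                                 n_noise_tfs = 200, seed = 1),
  rf_runs = 3, cv_folds = 5, cv_repeats = 1,
  boruta = boruta_config(n_iter = 100, ntree = 200),
  rfe = rfe_config(subset_start = 20, subset_step = 50),
  min_module_size = 10, seed = 1, output_dir = "example_run")

res <- run_pipeline(cfg, workflow = "all")
res$screen$consensus$consensus   # consensus regulator TFs of the target
res$grn$network                  # layered network over the DEG genes
```

## Known limitations

- The DEG stage's Welch test on log FPKM is a screening device, not a
  count-model inference; very low counts or heavy overdispersion call for
  a dedicated NB test plugged into the same interface.
- First-order conditioning cannot separate regulators whose expression is
  collinear beyond the proxy-pruning rule's reach; such TFs appear
  together, unoriented.
- The static tree cut can split or lump modules that dynamic cutting would
  resolve; module boundaries matter here only through the target's
  co-membership set.
- Edge signs (activation vs repression) are not annotated.
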