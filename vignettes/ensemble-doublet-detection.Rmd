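---
title: "Ensemble doublet detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble doublet detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chordsc)
```

## The problem and the model

Droplet-based scRNA-seq encapsulates cells in droplets at a dilution that
cannot prevent two cells from sometimes sharing a droplet. The resulting
doublets inherit the combined transcriptome of their two members and,
when the members are of different types, imitate intermediate cell states.
The doublet fraction grows roughly linearly with the number of loaded
cells; `estimate_doublet_rate()` encodes the standard loading rule of
0.9% per 1000 cells, capped at 0.5.

No single detection heuristic dominates across datasets, so `run_chord()`
stacks three complementary base scorers with a boosted meta-learner:

1. The **co-expression score** exploits marker exclusivity. After
   binarizing counts at `binThresh = 0` and keeping the `ntop = 500` genes
   with the largest binarized variance, each gene pair is weighted by the
   one-sided binomial evidence that it is *under*-co-expressed relative to
   independence (−log₁₀ of the lower binomial tail, only for pairs whose
   observed co-expression falls below expectation, capped at 300 to avoid
   numerical infinities). Cells that nevertheless co-express many such
   mutually exclusive pairs are doublet-like. The weight cap and min–max
   rescaling make the score scale-free in [0, 1].
2. The **pANN score** embeds real cells together with
   `round(pN/(1−pN)·n)` artificial doublets (unweighted pair means of raw
   counts; `pN = 0.25`) and measures, for each real cell, the proportion of
   artificial neighbours among its `k = round(pK·(n + n_sim))` nearest
   neighbours in 10-dimensional PC space. The neighbourhood fraction pK is
   not user-set: the grid {0.005, …, 0.3} is swept and the pK whose pANN
   distribution has the highest mean-variance-normalized bimodality
   coefficient wins. Both the raw BC and BCmvn are reported in the sweep
   table; BCmvn drives the selection because score distributions shift in
   mean across pK, and normalizing by the mean makes the bimodality signal
   comparable along the grid.
3. The **boosted score** trains depth-1 gradient-boosted trees to separate
   real cells from one artificial doublet per real cell, on log-normalized
   expression over the 500 most variable genes, and reports each real
   cell's out-of-fold probability of the artificial class (5 folds,
   re-folded up to five times if a fold degenerates to one class).

The meta-learner is trained on a simulated, labelled version of the input:
cells surviving an **overkill** pre-filter (per method, the top
`round(d·overkillrate·n)` scorers; the union removed; `overkillrate = 1`
by default) are clustered (30 PCs, k-means k = 20) and `round(N·d/(1−d))`
cross-cluster pairs are averaged into artificial doublets after weighting
each member by an independent N(1, 0.1) draw, truncated at zero. The same
three detectors score this training set, and 1000 boosted stumps at
shrinkage 0.01 (best iteration by 5-fold stratified CV deviance) learn the
combination. The fitted model then scores the *original* droplets, and the
top `round(d·n)` are called.

## Assumptions and their limits

- **Heterotypic focus.** Training doublets are cross-cluster pairs, so the
  model specializes in heterotypic doublets — the kind that distorts
  downstream analysis most. Homotypic doublets are largely invisible to
  every expression-based detector; `simulate_training_doublets()` exposes a
  `homotypic` flag but it is off by default.
- **The rate is an input.** Calling thresholds at `round(d·n)` trusts the
  supplied or loading-estimated rate; scores remain meaningful if the rate
  is off, but the binary calls inherit any rate error.
- **Mean-profile mixing.** Simulated training doublets are weighted means
  of member profiles, while physical doublets are closer to sums. The
  normalization step removes most of the depth difference, and the N(1, 0.1)
  weights mimic the residual biological/experimental wobble; the held-out
  synthetic sums are still recognized, which is the asymmetry the truth
  generator deliberately preserves (see below).

## The synthetic truth generator

`generate_truth()` emulates the ingredients the pipeline needs to be
testable without downloads: discrete cell types with negative-binomial
counts (gene base means log-normal(ln 0.5, 1.2²), dispersion 0.2), labelled
DEGs (fold change 2 applied in an assigned non-reference type; `round(frac ·
n_genes)` up and down labels), and ground-truth doublets formed as the
elementwise **sum** of two singlets of different types — the physical model
of two cells in one droplet, intentionally different from the training-set
simulation's weighted means. Summed doublets force the total-UMI dominance
seen in real data (doublets carry more UMI), which is asserted as an
invariant. Because both count conventions appear in common dataset
descriptions, the doublet budget can be specified as a fraction of the
final dataset (`count = round(N·d/(1−d))`) or of the singlets
(`count = round(d·N)`); each preset uses the convention that reproduces its
printed design counts.

`generate_trajectory_truth()` adds a bifurcating design: all lineages share
a progenitor program at pseudotime 0 and diverge along linear per-gene
log-fold gradients (20% of genes per lineage, slopes N(0, 0.8²)); singlet
pseudotime is uniform on [0, 1]. `subsample_gradient()` carves doublet-rate
gradients (e.g. 0.02–0.30 in steps of 0.02) out of a generated dataset by
sampling singlets and doublets without replacement.

What the generator does *not* emulate: ambient RNA, batch effects, library
chemistry artefacts, empty droplets, or realistic cell-type hierarchies.
Passing tests on this data show the machinery is correct and the
statistical directions (overkill helps; stacking does not lose to its best
base detector) hold under controlled conditions — not that real-data AUROC
will match.

## Numerical and design choices

- **Fold change in DEG calling** follows the convention of the dominant
  single-cell toolkit: the difference of log *group means* on the
  expression scale, `log(mean(expm1(x)) + 1)`, not the mean of logs. The
  mean-of-logs variant systematically understates fold changes for
  overdispersed counts and under-recovers the generator's labelled DEGs.
  Wilcoxon p-values use the exact distribution for small tie-free groups
  and the tie-corrected normal approximation otherwise (the `wilcox.test`
  default), Bonferroni-corrected over all genes in the matrix; `alpha = 1`
  disables the significance filter entirely (adjusted p-values clip at 1,
  so a strict inequality would silently drop saturated genes).
- **Partial AUC** is trapezoidal over FPR ∈ [0, 1−specificity] with linear
  interpolation at the boundary; the McClish standardization
  ½(1 + (pAUC − min)/(max − min)), max = 1−spec, min = max²/2, maps chance
  to 0.5 and perfection to 1 at every floor and agrees with the `pROC`
  reference implementation to 1e−10 on random instances (tested). Because
  published pAUC tables are often on this corrected scale while the raw
  area is bounded by 1−specificity, both forms are exposed.
- **AUPRC** uses continuous interpolation (linear in TP between operating
  points, precision integrated in closed form), so tied scores cannot
  inflate the area; an independent Riemann-sum oracle pins the
  implementation in the tests.
- **PCA** is exact (`prcomp`) up to 2000 cells and switches to seeded
  truncated SVD (`irlba`) above; component signs are fixed by making the
  largest-magnitude loading positive. **k-means** uses k-means++
  initialization with 10 restarts under a local RNG, so the whole chain is
  bit-reproducible given a seed. Nearest-neighbour ties and score ties at
  call cutoffs break by lower cell index, deterministically.
- **Variable genes** are ranked by the variance of clipped standardized
  counts under a degree-2 log-log polynomial mean–variance trend — a
  loess-free variant of the standard variance-stabilizing selection,
  chosen for determinism and rank-compatibility.
- **Per-cluster doublet budgets** `round(s_c·d/(1−d))` are adjusted by
  single draws at the largest clusters until the global budget
  `round(N·d/(1−d))` is exact, so 1000 singlets at d = 0.4 give exactly 667
  simulated doublets.
- **Gradient boosting** (both the bcds-analogue detector and the
  meta-learner) runs on `xgboost` with depth-1 trees, logistic loss and a
  single thread, which keeps results identical across machines. The
  stacker's settings (1000 trees, shrinkage 0.01, 5-fold CV) are the
  published ones; the detector uses 200 rounds at learning rate 0.2, enough
  for a saturating real-vs-artificial separation on the fixtures used.
- **Overkill** uses only the three built-in scores; external (stacking-
  only) columns do not influence the pre-filter, so the training set is
  reproducible from the seed before external tools ever run — that is what
  makes the two-phase external-scores workflow possible
  (`return_training_set = TRUE`, score externally, rerun with both tables).
- **Cluster stratification of pairs**: only the first member of a training
  doublet is stratified by cluster; the second is uniform over the other
  clusters. Stratifying both members would tilt pair-type frequencies away
  from the product of cluster sizes without a stated justification.
- The pK auto-selection refits on the training set rather than reusing the
  original matrix's pK: the training set has a different size and doublet
  fraction, and the selection statistic is cheap.

## Determinism and problem sizes

Every stochastic stage derives its own stream from the master seed, and
runs restore the caller's RNG state. Two runs with one config are
bit-identical end to end (tested). The test suite exercises the pipeline at
deliberately modest sizes — hundreds to two thousand cells, hundreds of
genes, ten-seed replications for the statistical properties — which keeps
the full suite in the minutes range while still leaving every detector
non-trivially challenged (the fixtures include 10–40% doublet fractions and
2–4 cell types).

## Known limitations

- The stochastic detectors (pANN, boosted) are deterministic given a seed
  but not invariant to column permutation of the input, because artificial
  doublet pairs are drawn by column index; only the co-expression score is
  exactly permutation-equivariant.
- Duplicating every cell changes the binomial background of the
  co-expression weights (n doubles), so ranks are preserved only
  approximately (Spearman ≥ 0.99 on the tested fixture), not exactly.
- Model persistence is a plain R object; no cross-version compatibility is
  promised.
- Single-seed DEG-recovery TPR on the generator's default design
  fluctuates by ±0.07 around ~0.82; the suite asserts the median over five
  fixed seeds.
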