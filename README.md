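# chordsc

Ensemble doublet detection for droplet-based single-cell RNA-seq.

In droplet platforms (10x Chromium and kin), a fraction of "cells" in the
count matrix are **doublets** — two cells that shared one droplet and one
barcode. Heterotypic doublets (two different cell types) masquerade as
intermediate or novel populations and distort clustering, differential
expression and trajectory inference. Individual doublet detectors behave
inconsistently across datasets; no single one is reliably best. `chordsc` is
for analysts who want a detector that is *stably* good: it stacks several
base scorers with a gradient-boosted meta-learner trained on simulated
doublets from the data at hand.

## The method

For a genes × cells UMI matrix with expected doublet rate *d* (by default
the loading rule *d* = 0.9% per 1000 cells):

1. **Base scoring.** Three built-in detectors score every droplet, higher =
   more doublet-like:
   - *co-expression score*: binarize counts, keep the `ntop = 500` genes with
     the largest binarized variance p̂(1−p̂), weight each gene pair (i, j) by
     the evidence of mutual exclusivity, w<sub>ij</sub> = −log₁₀ P[Bin(n, p̂ᵢp̂ⱼ) ≤ oᵢⱼ]
     when the observed co-expression count oᵢⱼ falls below its expectation
     (0 otherwise); a cell's score sums the weights of the exclusive pairs it
     co-expresses.
   - *pANN score*: simulate `pN/(1−pN)·n` artificial doublets (pair-averaged
     counts, `pN = 0.25`), co-embed everything (log-normalize → variable
     genes → scale → 10 PCs), and score each real cell by the fraction of
     artificial doublets among its k nearest neighbours; the neighbourhood
     fraction pK is auto-selected by the highest mean-variance-normalized
     bimodality coefficient BC = (g₁² + 1)/(g₂ + 3(n−1)²/((n−2)(n−3))).
   - *boosted score*: out-of-fold probability from gradient-boosted stumps
     trained to separate real cells from artificial doublets.
2. **Overkill.** For each base method, the top `d · overkillrate · n` cells
   are marked and the union removed, so real doublets stay out of the
   "singlet" training class.
3. **Training-set simulation.** The prefiltered cells are clustered (PCA to
   30 components, k-means k = 20); `round(N·d/(1−d))` artificial doublets are
   drawn as cross-cluster pairs, each member weighted by an independent
   N(1, 0.1) biological factor, profiles averaged.
4. **Stacking.** The same base detectors score the training set; a boosted
   stacker (1000 depth-1 trees, shrinkage 0.01, best iteration by 5-fold CV
   deviance) learns to combine them, with simulated doublets as positives.
5. **Scoring & calling.** The model scores the original droplets; the top
   `round(d·n)` are called doublets.

External per-cell score tables (e.g. Scrublet or DoubletDetection run
elsewhere) can ride along as extra stacking features — supply scores for
both the original matrix and the (reproducible) training set.

The package also ships a ground-truth synthetic data generator
(negative-binomial counts, labelled heterotypic doublets as member-count
*sums*, DEG truth labels, bifurcating trajectories, doublet-rate gradients)
and the full evaluation toolkit (AUROC, AUPRC, standardized partial AUC,
rank-stability SDrank, Wilcoxon DEG calling with fold-change/detection/
Bonferroni filters).

## Worked example

```r
library(chordsc)
library(dplyr)

# a labelled two-type dataset: 300 singlets + 10% heterotypic doublets
td <- generate_truth(n_types = 2, cells_per_type = 150, n_genes = 400,
                     doublet_frac = 0.1, rate_convention = "singlets", seed = 3)
res <- run_chord(td$counts, chord_config(doubletrate = 0.1, seed = 42))
res
#> <chord_result>
#>   330 cells, doublet rate 0.1000, 33 called doublets
#>   features: coexpression, knn, boosted
#>   overkill removed 49 cells; booster best iteration 1000 (train AUROC 1.000)

tidy(res) |> arrange(desc(chord)) |> head(3)
#> # A tibble: 3 × 6
#>   cell_id       coexpression   knn boosted chord is_doublet_call
#>   <chr>                <dbl> <dbl>   <dbl> <dbl> <lgl>
#> 1 doublet_00001        0.822   1     0.975 0.967 TRUE
#> 2 doublet_00002        0.797   1     0.921 0.967 TRUE
#> 3 doublet_00003        0.804   0.5   0.929 0.967 TRUE

metric_panel(tidy(res)$chord, td$cells$is_doublet)
#> # A tibble: 1 × 6
#>   auroc auprc pauc800 pauc900 pauc950 pauc975
#>   <dbl> <dbl>   <dbl>   <dbl>   <dbl>   <dbl>
#> 1     1     1       1       1       1       1
```

The `chord` column is the stacked probability that a droplet is a doublet;
`is_doublet_call` flags the top `round(d·n)` cells. On this small labelled
fixture the ensemble ranks every true doublet above every singlet (AUROC 1);
on harder data expect values in the 0.7–0.95 range. `autoplot(res)` shows the
per-method score distributions, `plot_roc()` the ROC curves.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/chord simulate --types 2 --cells-per-type 200 --genes 500 \
    --doublet-rate 0.1 --seed 1 --out sim/
Rscript inst/cli/chord run --counts sim/matrix.mtx --doublet-rate 0.1 \
    --seed 1 --out out/
Rscript inst/cli/chord evaluate --scores out/scores.csv --labels sim/labels.csv \
    --out metrics.csv
```

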