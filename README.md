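# grrann

Binary phenotype prediction from gene expression with a **gene-regulatory-
network-constrained, regularized neural network**, for settings where
measured genes vastly outnumber subjects (clinical transcriptomic cohorts)
and purely data-driven classifiers overfit and fail to reproduce across
independent trials.

The classifier is a single-hidden-layer network wired by a regulatory
network: input nodes are genes, hidden nodes are their upstream regulators,
and a gene feeds a regulator's hidden unit **iff** the regulator→gene edge
exists. With ReLU hidden units and a sigmoid output,

```
ŷ = σ( W⁽²⁾ · max(0, W⁽¹⁾x + b⁽¹⁾) + b⁽²⁾ )
```

training minimizes the mean cross-entropy plus the mixed penalty

```
g(α, λ, W) = α λ ‖W⁽¹⁾‖²₂ + (1−α) λ Σᵢ √ρᵢ |W⁽²⁾ᵢ|
```

where ρᵢ is regulator *i*'s in-degree. The ℓ1 term is a group lasso at the
hidden layer: zeroing one output weight silences a regulator and its whole
gene set (group drop-out, with gene-set overlap handled for free by the
architecture), while the ridge term pulls co-regulated, correlated genes
toward similar weights. Optimization is full-batch proximal gradient descent
with backtracking — the ℓ1 terms are soft-thresholded, so zeros are exact
and the penalized objective never increases.

The package covers the full workflow: edge-list parsing and gene-universe
alignment, sign-filtered and randomized (negative-control) architectures,
λ grid search anchored at the group-lasso saturation point
(λ_min = 0.1 λ_max), stratified cross-validation with balanced accuracy,
independent train/test cohort evaluation, bootstrap stability ranking of
regulators, and a synthetic-data generator with planted active regulators so
everything is testable offline. A command-line front end
(`inst/cli/grrann`) exposes `simulate` / `train` / `evaluate` / `bootstrap` /
`randomize-net` with reproducible run manifests.

## Worked example

Simulate the reference study (50 regulators over a 1500-gene universe, 5
active regulators shifting their gene sets by 3 sd of latent activity,
n = 200), select λ, fit, cross-validate, and rank regulator stability:

```r
library(grrann)

spec <- simulation_spec(seed = 1)
net  <- simulate_network(spec)
sim  <- simulate_dataset(net, spec)
arch <- build_architecture(net)
arch
#> Network architecture: 593 genes -> 50 regulators -> 1 output
#>   connections:750 (density 0.0253)
#>   in-degree rho: min 15 median 15 max 15

search <- lambda_search(sim$x, sim$y, arch, grid_size = 6, seed = 2,
                        control = grrann_control(max_epochs = 500, tol = 1e-6))
search$path
#>       lambda mean_balanced_accuracy nonzero_w2
#> 1 0.01000000              0.9544087          4
#> 2 0.01584893              0.9547011          4
#> 3 0.02511886              0.9295967          4
#> 4 0.03981072              0.8296917          3
#> 5 0.06309573              0.7189109          0
#> 6 0.10000000              0.5000000          0

fit <- grrann(standardize(sim$x), sim$y, arch, lambda = search$best_lambda,
              control = grrann_control(seed = 3))
summary(fit, n_top = 3)
#> Network-constrained regularized neural net (grrann)
#>   593 genes -> 50 regulators -> 1 output; 750 connections
#>   lambda = 0.01584893, alpha = 0.5
#>   active regulators: 3 / 50  (47 dropped)
#>   objective 0.196644 after 105 epochs (converged)
#>   training balanced accuracy: 0.9899
#> Top regulators by |output weight|:
#>   regulator  weight rho
#> 1       r37 -1.1727  15
#> 2       r16  1.0384  15
#> 3       r23 -0.8928  15

cv_grrann(sim$x, sim$y, arch, k = 5, lambda = search$best_lambda, seed = 4)
#> 5-fold CV (grrann, lambda = 0.01584893)
#>   fold balanced accuracies: 0.951, 0.955, 0.876, 0.869, 0.944
#>   mean balanced accuracy: 0.9191

boot <- bootstrap_stability(sim$x, sim$y, arch, lambda = search$best_lambda,
                            num_runs = 100, top_k = 10, seed = 5,
                            control = grrann_control(max_epochs = 500, tol = 1e-6))
boot
#> Bootstrap stability report: 100 runs, top 10
#>   most frequent regulators:
#> r07 r37 r23 r16 r26 r25 r03 r10 r13 r33
#>  64  64  55  54  45   5   2   2   2   2
sim$active_regulators
#> [1] "r07" "r16" "r23" "r26" "r37"
```

Reading the output: the λ path shows the group-lasso support shrinking to
empty at λ_max = 0.1 with the CV-best value just above λ_min; the fitted
model keeps 3 of 50 regulators (all true positives) and classifies held-out
folds at 0.92 balanced accuracy; across 100 bootstrap refits the five most
frequently top-ranked regulators are exactly the five planted active ones,
well separated from the background.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "grrann", package = "grrann"))')
Rscript $CLI simulate --seed 1 --out study/
Rscript $CLI train --network study/network.tsv --expression study/expression.tsv \
    --labels study/labels.tsv --lambda search --out model/
Rscript $CLI bootstrap --network study/network.tsv --expression study/expression.tsv \
    --labels study/labels.tsv --lambda 0.016 --runs 100 --out boot/
```

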