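---
title: "Network-constrained regularized neural networks for phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-constrained regularized neural networks for phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`grrann` predicts a binary phenotype (responder / non-responder, rejection /
no rejection) from a gene-expression profile while using a gene regulatory
network (GRN) as a structural prior. The classifier is a single-hidden-layer
neural network whose wiring is dictated by the GRN:

* **input nodes are genes**, one per measured gene present in the network;
* **hidden nodes are regulators** (transcription factors, miRNAs, compounds);
* an input node is connected to a hidden node **if and only if** the network
  contains the corresponding regulator-to-gene edge;
* a single sigmoid output node is fully connected to the hidden layer.

With $W^{(1)}$ the masked gene-to-regulator weights, $W^{(2)}$ the
regulator-to-output weights, ReLU hidden activations $f_1(z) = \max(0, z)$
and a sigmoid output $f_2$, the prediction for a standardized expression
vector $x$ is

$$\hat y = f_2\!\left(W^{(2)} f_1\!\left(W^{(1)} x + b^{(1)}\right) + b^{(2)}\right).$$

Training minimizes the mean cross-entropy (negative Bernoulli
log-likelihood) plus a mixed penalty

$$g(\alpha, \lambda, W) \;=\; \alpha\lambda\,\|W^{(1)}\|_2^2 \;+\;
(1-\alpha)\lambda \sum_i \sqrt{\rho_i}\,\bigl|W^{(2)}_i\bigr|,$$

where $\rho_i$ is the in-degree (number of target genes) of regulator $i$.
The second term is a group lasso at the hidden layer: each regulator carries
one output weight, and driving $W^{(2)}_i$ to exactly zero silences the
regulator's entire gene set at once — its $W^{(1)}$ row can no longer
influence the output, so the group drops out of the fit without any of the
machinery that overlapping-group lasso needs in regression (a gene shared by
several regulators is removed only through its inactive edges). The
$\sqrt{\rho_i}$ factor shrinks large gene sets more, the usual group-size
weighting. The ridge term on $W^{(1)}$ provides the elastic-net effect:
co-regulated genes have correlated expression, and the quadratic penalty
assigns them similar weights, lowering model variance. Biases are never
penalized.

The mask-induced sparsity is the point of the design: the parameter count is
the number of network edges plus one weight per regulator, orders of
magnitude below a dense network, which is what makes fitting feasible at
clinical-trial sample sizes (tens to hundreds of subjects against thousands
of genes).

### Penalty variants (ablations)

`variant =` selects the penalty used, reproducing the method's ablation
panel:

| variant   | $W^{(1)}$ term                  | $W^{(2)}$ term                              |
|-----------|---------------------------------|---------------------------------------------|
| `grrann`  | $\alpha\lambda \sum w^2$        | $(1-\alpha)\lambda \sum \sqrt{\rho_i}|w_i|$ |
| `half_l2` | $\lambda \sum w^2$              | none                                        |
| `half_l1` | none                            | $\lambda \sum \sqrt{\rho_i}|w_i|$           |
| `full_l1` | $\alpha\lambda \sum |w|$        | $(1-\alpha)\lambda \sum \sqrt{\rho_i}|w_i|$ |
| `full_l2` | $\alpha\lambda \sum w^2$        | $(1-\alpha)\lambda \sum \sqrt{\rho_i}w_i^2$ |

`half_l2` and `half_l1` correspond to $\alpha = 1$ and $\alpha = 0$
respectively, so they apply the full $\lambda$ to their surviving term. The
default tradeoff is $\alpha = 0.5$, also used in the `full_l1` / `full_l2`
comparisons.

### Design choices worth knowing

* **Squared ridge.** $\|W^{(1)}\|_2$ is implemented as the squared
  sum of squares — it is described as a ridge penalty, and the squared form
  keeps the term smooth. The unsquared Frobenius-norm reading is available
  via `grrann_control(squared_l2 = FALSE)`.
* **Loss sign.** The Bernoulli log-likelihood is maximized, i.e. the
  *negative* log-likelihood is the minimized loss.
* **Predictions.** Probabilities at or above `threshold` (default 0.5) are
  labelled 1, so an all-zero model labels everything 1; documented boundary
  convention.

## Optimization

No optimizer is inherent to the model, so the package uses the method that
makes the group drop-out semantics exact: full-batch **proximal gradient
descent** with backtracking line search. The smooth part (cross-entropy +
all $\ell_2$ terms) is differentiated by backpropagation with the $W^{(1)}$
gradient masked; the $\ell_1$ terms are applied through their proximal map
(soft-thresholding), which produces *exact* zeros rather than numerically
small weights. Each accepted step satisfies the quadratic-majorizer
condition, so the penalized objective is non-increasing epoch over epoch —
a property the test suite asserts. Defaults: `learning_rate = 0.05`
(initial step; backtracking halves it as needed, and it re-grows by 1.2×
per epoch, capped at 10), `max_epochs = 2000`, `tol = 1e-7` on the
objective improvement.

Weight initialization is He-style on the masked support
(sd $\sqrt{2/\rho_i}$ per regulator row, ReLU-appropriate), small Gaussian
(sd 0.01) output weights, zero biases, all reproducible under
`grrann_control(seed = )`. Predictions are clipped to
$[10^{-12}, 1-10^{-12}]$ inside the loss to keep logarithms finite.
`zero_eps = 1e-8` is only a *reporting* threshold for which regulators count
as dropped; training itself yields exact zeros. ReLU subgradient at 0 is
taken as 0. Mini-batching is deliberately not offered: the descent guarantee
and exact-zero semantics are full-batch properties, and the intended sample
sizes (tens to hundreds) make full batches cheap.

## The λ protocol

$\lambda$ is set by a saturation-anchored grid search
(`lambda_search()`): sweep upward by factors of 10 from 0.01 until a
full-data fit drives **every** output weight to zero — that value is
$\lambda_{max}$ — then set $\lambda_{min} = 0.1\,\lambda_{max}$ and score a
log-spaced grid between them by mean 5-fold cross-validated balanced
accuracy, breaking ties toward the larger (sparser) $\lambda$. The same fold
assignment is reused across the grid; no nested CV is performed, so the
reported path accuracy is mildly optimistic and is labelled as such. The
saturation anchor requires an $\ell_1$ term on $W^{(2)}$; for the ridge-only
ablations, whose output weights never reach exact zero, pass an explicit
`grid` (for example the grid of a `grrann` search on the same data).

## Evaluation protocol

* **Standardization**: every gene column to mean 0, sd 1 (population sd,
  `ddof = 0`; configurable). Constant columns become zeros with a warning.
  Training and test data are *always* standardized separately on their own
  statistics — never with shared statistics — matching how independent
  cohorts must be processed in practice; the test suite asserts that
  altering the test set cannot change fitted weights.
* **Cross-validation** (`cv_grrann()`): stratified $k$-fold (default 5).
  Stratification is not strictly implied by a plain "k-fold" description but
  protects the small-cohort regimes (n ≈ 22) this method targets.
* **Metric**: balanced accuracy, (sensitivity + specificity)/2 — 0.5 for any
  constant predictor regardless of class imbalance.
* **Independent testing** (`independent_test()`): train on one cohort, test
  on another; the CV-to-test drop measures generalization.

## Ablation machinery

`randomize_architecture()` keeps both node sets and the total connection
count fixed but redraws the edges uniformly at random without duplicates —
the negative control quantifying what the true regulatory topology
contributes. Uniform redraw is the simplest model consistent with
"connections randomized, nodes identical"; a per-regulator degree-preserving
variant sits behind `degree_preserving = TRUE` for sensitivity analysis.
Shuffles retain some true edges by chance; the retained count is attached as
the `"overlap"` attribute. Regulators left with no connections are kept (the
node sets must stay identical) and listed in `zero_rho`.

## Bootstrap stability

`bootstrap_stability()` resamples the training data with replacement
(default 100 runs), refits at a *fixed* $\lambda$ — selected once on the
full dataset; re-searching per resample would multiply cost by the grid size
and change the question being asked — and ranks regulators by
$|W^{(2)}_i|$, ties broken by regulator id for determinism. The report
counts appearances in the top 10 (only regulators with nonzero output weight
can occupy top slots), and flags regulators above the 0.75 frequency
quantile (configurable) as the stable set. The TSV export feeds downstream
heat-mapping or gene-set enrichment tooling directly.

## The synthetic study

Because the method's real inputs are clinical cohorts, the package carries a
first-class generator (`simulation_spec()`, `simulate_network()`,
`simulate_dataset()`) so every claim is testable offline. The generative
model: a bipartite GRN with `edges_per_regulator` targets per regulator and
uniform ± signs; latent per-sample regulator activities $a_r \sim N(0,1)$,
with `effect_size` added to the activities of the planted active regulators
in class-1 samples; gene expression

$$x_g = \sum_{r \to g} \mathrm{sign}(r,g)\,\sqrt{c}\; a_r + \varepsilon_g,
\qquad \varepsilon_g \sim N(0, \sigma^2),$$

with $c$ = `within_group_correlation`. Labels causally precede activities so
the classification direction (expression → phenotype) matches the use case
while the data-generating direction is regulator-driven, matching the
model's assumption. With `effect_size = 0` each gene's variance has the
closed form $c\,\rho^{in}_g + \sigma^2$, which the tests verify at
n = 10,000.

**Reference design** (the generator defaults, used by the acceptance-level
tests and `scripts/acceptance.R`): 50 regulators, 15 targets each drawn from
a 1500-gene universe (≈600 genes end up connected and measured, so measured
genes outnumber the n = 200 balanced samples), 5 active regulators, effect
3 sd, $c = 0.05$, $\sigma = 1$. The weak per-gene loading is deliberate: a
single target gene then carries a class separation of only ≈0.65 sd while a
regulator's full gene set aggregates to ≈3 sd, so reliable classification
requires pooling each regulator's group — the high-dimensional,
weak-marker regime of transcriptomic cohorts in which a structural prior
has value. (In an earlier, easier design with 100 genes and n ≥ genes, even
a shuffled-mask model classified at ~0.9 balanced accuracy and the
architecture ablation could not show its effect.) Study-scale runs in the
tests use `max_epochs = 500`, `tol = 1e-6`, 5-fold CV, and 50 bootstrap
runs; these sizes are the package's reference configuration for this
design.

What the generator does **not** emulate: microarray technical artifacts
(probe effects, batch effects, presence calls), heavy-tailed or count-like
expression distributions, regulator–regulator correlation, and label noise.
Passing tests therefore demonstrate correctness of the machinery and
qualitative behavior of the penalties under the generative assumptions, not
clinical performance.

## Known limitations

* On this clean Gaussian design with the *true* mask and n = 200, the
  ridge-only ablations (`half_l2`, `full_l2`) are strong: dense ridge over
  50 informative group-aggregate hidden units is not handicapped, and in the
  package's own variant panel it edges out the mixed ℓ2–ℓ1 penalty by a few
  points of balanced accuracy. The advantage of group sparsity claimed for
  real cohorts rests on far larger hidden layers, smaller samples, and
  signal that is sparse in regulator space; the synthetic panel reproduces
  the ordering against the ℓ1 ablations but not against the ridge-only
  ones.
* The λ grid spans only $[0.1\lambda_{max}, \lambda_{max}]$ with
  $\lambda_{max}$ found on a decade-coarse sweep, so the selected λ can sit
  at the grid boundary; widen `grid_size` or supply `grid` if the path looks
  truncated.
* Identifier matching between network and expression files is exact
  (whitespace-trimmed, case-preserving); no alias resolution is attempted.
* One hidden layer only; multi-level regulatory hierarchies are out of
  scope.

## A minimal session

```{r example}
library(grrann)

spec <- simulation_spec(seed = 1)
net  <- simulate_network(spec)
sim  <- simulate_dataset(net, spec)
arch <- build_architecture(net)

search <- lambda_search(sim$x, sim$y, arch, grid_size = 6, seed = 2)
fit <- grrann(standardize(sim$x), sim$y, arch, lambda = search$best_lambda,
              control = grrann_control(seed = 3))
summary(fit)

cv <- cv_grrann(sim$x, sim$y, arch, k = 5, lambda = search$best_lambda,
                seed = 4)
cv

boot <- bootstrap_stability(sim$x, sim$y, arch,
                            lambda = search$best_lambda,
                            num_runs = 100, top_k = 10, seed = 5)
boot
sim$active_regulators   # ground truth to compare against
```
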