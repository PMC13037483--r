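---
title: "Methods: QSRR retention-time modelling in gcqsrr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSRR retention-time modelling in gcqsrr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gcqsrr)
library(dplyr)
```

## The modelling problem

Quantitative structure–retention relationship (QSRR) models predict the
gas-chromatographic retention time (RT, minutes) of a compound from
numeric molecular descriptors. The workflow this package implements is
the one standard in forensic GC screening of basic drugs on non-polar
columns: a large descriptor pool is first pruned of degenerate and
redundant columns, a genetic algorithm (GA) then searches for a compact
informative subset, and the final regression is fitted either linearly
(partial least squares, PLS), through a Gaussian kernel (KPLS), or with
a small neural network trained by Levenberg–Marquardt (LM-ANN). Internal
validity is assessed by leave-group-out cross-validation (LGO-CV) and
external validity on a held-out test set.

The package ships one real dataset (`load_drug_rt()`): 75 narcotic and
hazardous drugs with RTs between 0.96 and 2.16 min measured on an HP-5
column, a fixed 60/15 train/test split, and three bulk physicochemical
descriptors (molecular weight, XlogP3, hydrogen-bond donor count). Full
descriptor matrices of thousands of columns are not shipped; they come
from descriptor software and are supplied by the user as CSV. All
structural claims of the workflow are therefore tested on synthetic data
with known ground truth.

## What the generator emulates — and what it does not

`simulate_qsrr()` reproduces the statistical features the pipeline must
survive:

* **High dimensionality and collinearity.** Descriptors are drawn in
  equicorrelated Gaussian blocks via the shared-factor construction
  $x = \sqrt{\rho}\, z_{\mathrm{block}} + \sqrt{1-\rho}\,\varepsilon$,
  giving an exact target correlation $\rho$ (default 0.9) with no
  covariance factorization edge cases.
* **Sparse truth.** `n_true` informative columns are planted, exactly
  one per correlated block, so the $|r| > 0.90$ pre-filter cannot delete
  the whole truth no matter which pair member it keeps.
* **Degenerate columns.** Constant columns, and near-constant columns
  whose modal value occupies more than 95% of rows, are appended last —
  the cases the pre-treatment stage must catch.
* **A retention-like response.** The noiseless surface (linear
  $X\beta$, or additive tanh plus one bilinear interaction among the
  informative columns, $\gamma = 0.5$) is affinely rescaled into the
  0.9–2.2 min range of the packaged dataset before Gaussian noise is
  added. The default noise of 0.03 min is an implementer choice — about
  1.5–3% of the RT span, a plausible run-to-run reproducibility for a
  temperature-programmed GC method; no measured value was available.

The generator does **not** simulate real molecular descriptors (no
radial-distribution functions, topological indices or quantum-chemical
quantities) and no chromatographic physics. Passing tests on synthetic
data therefore demonstrate that the *algorithms* behave as specified
(recovery of planted truth, calibration of metrics, determinism), not
that any particular descriptor set predicts RT for new chemistry.

## Pre-treatment

`pretreat()` applies three passes on the training rows only (test rows
never influence the filter): zero-variance removal, near-constant
removal (modal frequency ≥ 0.95 — "near-constant" has no universal
definition, this is the common chemometrics convention and is
testable), and a greedy scan of descriptor pairs with $|r| > 0.90$.
Which pair member is dropped is deterministic: by default the member
less correlated with the response goes (preserving predictive signal);
with `response_aware = FALSE` the later column goes. The procedure is
idempotent. Autoscaling (`fit_scaler()`) uses training means and
standard deviations with the $n-1$ denominator, stated so tests can be
exact.

## The regression cores

**PLS.** `nipals_pls()` implements NIPALS deflation. With a single
response the weight vector of each component is the normalized
covariance $X^\top y$, so extraction is non-iterative and exact;
successive scores are orthogonal by construction, and with full latent
rank the fit equals ordinary least squares — the oracle used in the
tests. The default of 4 latent variables is the convention for compact
linear GC retention models and is configurable; no automatic component
selection is attempted because the choice is a reporting convention,
not a derived quantity.

**KPLS.** `rbf_kernel()` is the Gaussian kernel
$\exp(-\|x_i - x_j\|^2 / (2\sigma^2))$. The width convention
(σ versus 2σ²) is absorbed by `choose_sigma()`, which minimizes
cross-validated RMSE over a grid of multipliers of the median pairwise
training distance, breaking ties toward the smaller width.
`kpls_fit()` double-centers the kernel, extracts components by iterated
score updates (cap 500 iterations, tolerance $10^{-10}$ on the score
change — values needed for determinism, not given by any reference) and
deflates with $K \leftarrow (I - tt^\top) K (I - tt^\top)$. Whether to
center the kernel at all is a genuinely open choice in the literature;
double-centering is adopted because it makes the linear-kernel case
coincide exactly with PLS, which the test suite exploits as an oracle.
The default of 3 latent variables mirrors compact nonlinear retention
models.

**LM-ANN.** One tanh hidden layer, linear output. Training is
full-batch damped Gauss–Newton: each epoch solves
$(J^\top J + \lambda I)\,\Delta w = J^\top e$ and accepts the step only
if the training SSE decreases (λ ×0.1 on acceptance, ×10 on rejection;
a λ overflow past $10^{10}$ is a converged stall, not an error), so
accepted steps never increase the training loss — an invariant the
tests assert per epoch. The Jacobian is analytic and validated against
central finite differences. Early stopping watches validation RMSE with
patience 10 and returns the best-validation weights. A note on
conventions: LM has no learning rate, so a conventionally quoted
"learning rate of 0.01" for such networks is interpreted here as the
initial damping $\lambda_0 = 0.01$ — the only self-consistent reading.
Weight initialization is U(−0.5, 0.5) from a seeded generator. Epochs
default to 150 with a hard cap of 200 (the scan limit);
`select_hidden()` scans 2–10 hidden units with at least 3 restarts per
size and picks the lowest median validation RMSE (ties to fewer
neurons); `ann_restarts()` repeats training 15 times for mean ± sd
stability reporting. For the packaged dataset's dimensionality (7
inputs, 4 hidden) the network has 37 weights against 60 training
compounds — deliberately small to keep the parameter/sample ratio
favourable.

**Sensitivity analysis.** `ann_sensitivity()` perturbs each
*standardized* input multiplicatively by ±5% and ±10% with the others
fixed and averages |Δ predicted RT| over compounds and model
realizations. Because the perturbation is multiplicative in scaled
space, an entry exactly at the training mean (scaled value 0)
contributes zero — documented, intended behaviour.

## GA descriptor selection

Chromosomes are binary inclusion masks. Defaults: population 30,
single-point crossover with probability 0.5, per-gene mutation 0.01, at
most 1000 generations, stall stop after 100 generations without an
improvement of at least 0.001, 20 independent runs. Where the
literature leaves operators open, standard parameter-light choices are
made and stated: tournament selection of size 2; elitism 1 (which also
guarantees the monotone best-fitness trace the invariant tests rely
on); initial per-bit inclusion probability 0.1, mirroring the parsimony
goal; empty chromosomes repaired by activating one random bit.

The fitness unifies the two common formulations (minimize RMSECV /
maximize Q²), which are monotone transforms of each other under fixed
folds: `ga_fitness()` returns $Q^2_{cv} - \alpha\,k/K$ with α = 0.05,
$Q^2_{cv} = 1 - \mathrm{PRESS}/\mathrm{TSS}$ from an inner 5-fold CV of
the wrapped estimator (PLS by default; leave-one-out is available by
setting `inner_folds` to the row count). The fold assignment is fixed
per run so fitness values are comparable across chromosomes; the
scaler is refit inside every fold. Estimator failure on a degenerate
mask yields −∞ and the chromosome is culled.

`ga_consensus()` reports per-descriptor selection frequency over the
run-best masks — the primary stability metric — and picks as final mask
the run-best mask with the highest re-evaluated CV fitness under a
fresh fold assignment (ties: higher mean member frequency, then smaller
mask).

## Validation

`regression_metrics()` computes MSE, RMSE, R², adjusted R², SE and
Pearson r. SE is the sample standard deviation of the residuals — the
only residual-based definition that is internally consistent — and
adjusted R² uses $p$ = number of input descriptors (configurable),
since no alternative convention reproduces published tables any
better. `lgo_cv()` shuffles rows into contiguous groups of about 7
compounds (the conventional 5–10 range; structural-similarity grouping
is out of scope because no structures are shipped), refits the model
including its scaler with each group held out, and reports Q² and
RMSECV. `y_scramble()` permutes the response to verify that fitness
collapses — the standard guard against chance correlation.

## Pipeline, seeds and problem sizes

`run_qsrr_pipeline()` chains load/simulate → partition → pretreat → GA
→ fit → validate, writing every artifact plus a manifest with MD5
checksums. Every stage seed is derived from the master seed by a small
deterministic hash, so whole runs reproduce bit for bit — asserted by
the test suite. For an ANN final model the LGO-CV block refits the PLS
estimator on the selected descriptors rather than a 15-restart network
per fold; the network's own validation and test partitions carry its
honest error estimate.

Two partition schemes are provided because linear/kernel models use the
fixed 80/20 split printed with the packaged dataset, while the ANN
needs a validation set: `stratified_70_15_15` sorts by response, forms
consecutive strata of about 7 rows, and samples within strata with
cumulative rounding so the global 70/15/15 counts are exact and every
part of the RT distribution reaches all three sets. Which specific
compounds would form an ANN test set in any published analysis is not
reconstructible; the scheme here is seeded and documented rather than
guessed.

The test suite and examples run at deliberately reduced sizes chosen to
exercise every code path while keeping a full run of suite plus
acceptance script in a few minutes: GA recovery uses K = 50 descriptors
(ρ = 0.9 blocks, 5 planted, 20 runs × 100 generations), the exhaustive
GA oracle uses K = 10, the ANN stability checks use n = 75 compounds —
the scale of the packaged dataset.

## Known limitations

* The correlation pre-filter is greedy and order-dependent in
  principle; the response-aware tie rule makes it deterministic but a
  different scan order could keep a different (equally valid) subset.
* Q² uses the overall response mean in TSS; alternative conventions
  (per-fold training means) differ slightly for small groups.
* The LM-ANN fits small networks only; multi-layer topologies and
  stochastic optimizers are out of scope.
* Sensitivity rankings are descriptive, not causal: collinear
  descriptors share credit in an unidentifiable way.
* Model performance numbers obtained on the packaged three-descriptor
  table are illustrative; serious retention prediction requires a full
  descriptor matrix supplied by the user.
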