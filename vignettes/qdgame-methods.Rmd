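---
title: "Quasi-dynamic ODE game models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-dynamic ODE game models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdgame)
```

## The problem

Paired single-cell expression data — a gene measured in two interacting cell
populations (for instance fetal germ cells and their surrounding somatic
niche cells) across a set of embryos — are static snapshots. qdgame converts
them into quasi-dynamic ordinary differential equation (qdODE) systems whose
"time" axis is not time but an expression-derived index: the **niche index**
`N = g1 + g2` (the gene's total expression over both cell types in a unit)
for two-player models, or the **expression index** (a sample's total
expression over genes, or a gene's total over cells) for network models.
Because units differ in their index value, ordering them along the index
turns cross-sectional heterogeneity into a trajectory, and ODEs in the index
variable can be fitted without temporal data.

## The model

Each variable's index-derivative is split into two game-theoretic parts:

* an **independent component**: the derivative of an allometric power law
  `g(N) = alpha * N^beta`, i.e. `alpha * beta * N^(beta-1)` — what the
  player would express in isolation. Allometric (part-whole) scaling
  justifies the power form; empirically, log-log regressions of expression
  on the index are close to linear.
* **dependent components**, one per directed influence: a Legendre
  polynomial (LOP) series evaluated at the *source's* current value after
  affine mapping onto `[-1, 1]`. The constant Legendre term is excluded
  (orders `1..r`, default `r = 3`, selectable by AIC among 2-4): a constant
  dependent rate cannot be separated from the independent power term.

Integrating each rate term separately along the index yields the
decomposition `mean = independent + sum(dependent)`; the package integrates
all components in one fourth-order Runge-Kutta pass (sub-stepped so that no
step exceeds 1/100 of the grid span), so the identity holds at machine
precision by construction. The sign of a dependent integral at the top of
the index range (`net_dep`) is read as activation (+) or inhibition (-) of
the target by the source.

For a paired profile the residuals of the two cell types follow a bivariate
AR(1) model along the index ordering: block `k` has covariance
`sigma_k^2 * rho_k^|i-j|`, and the cross block decays with the geometric
mean `sqrt(rho1*rho2)` scaled by `rho12`. This choice of cross decay is the
package's own (the functional form is otherwise unconstrained); positive
definiteness is verified by Cholesky factorization and a failure is
reported as `rho12` too large. The likelihood is the multivariate normal
density of the stacked residuals, maximized over all power, Legendre, and
AR(1) parameters.

## Estimation

Optimization works on an unconstrained scale (`log alpha`, `log sigma`,
`atanh` of correlations with `|rho|` bounded at 0.95 — see *Numerical
choices*). The optimizer is Nelder-Mead (restarted from its own optimum
until improvement stalls) followed by a BFGS polish with central-difference
gradients; pure Nelder-Mead reliably stalls far from the optimum in the
13-15 parameter full model, which is why the polish stage exists. Fits are
multi-started:

1. a **regression-seeded chain**: with each partner pinned to its observed
   series, the dependent curves are linear in the Legendre coefficients, so
   a lightly ridge-regularized least-squares profile of the data on
   `[power column, basis integrals]` gives coefficient seeds;
2. a **null-padded chain** starting from the no-interaction optimum with
   zero coefficients (this guarantees the full model attains at least the
   null likelihood, so the likelihood ratio is never negative);
3. optional moment-seeded chains with seeded jitters.

Later chains replace the incumbent only when they improve the
log-likelihood by more than 0.5 nats. This rule is an identification
device: the likelihood is nearly flat along trade-offs between the power
term and smooth dependent curves (see *Limitations*), and without it the
reported decomposition would be decided by optimizer noise.

The interaction test is the likelihood ratio `LR = -2 log(L0/L1)` between
the no-interaction (non-game) and full (game) fits, calibrated by
permutation; both models are refitted on each of `n_perm` permuted datasets
(1000 by default) with the same settings as the observed fit, and the
threshold is the 95th percentile of the permuted LR values. The default
scheme whitens the null-fit residuals with the fitted AR(1) factor,
permutes the innovations across positions, recolors, and adds them back to
the no-interaction means, so every permuted dataset carries the marginal
curves and the error correlation but no interaction structure. A
label-swap scheme (the two cell types exchanged within a unit with
probability 1/2, preserving the niche index exactly) is available as an
option, but it is only calibrated when the two marginal curves are
exchangeable: when they differ, the swap itself manufactures apparent
interaction, inflating the permutation threshold and destroying power —
this was measured directly on synthetic data, which is why it is not the
default. Genome-wide screens pool permuted LR values across genes into a
single shared threshold.

## Networks

For m-variable systems (genes within a cell type, modules, or cells within
an embryo) the package first reduces dimension: power-equation-based
functional clustering (an EM-fitted mixture whose component means are power
curves, one per module per cell type, with module-specific Gaussian
residual variances; AIC selects the module count), then per focal variable
an adaptive LASSO over the candidates' Legendre basis-integral columns
(grouped per candidate, penalty by cross-validation, `glmnet`), capped at
`max_predictors`. Each node's reduced qdODE is then fitted in decoupled
mode: the selected sources are pinned to the linear interpolants of their
*observed* series. The per-sample fluctuations of a source are precisely
what identifies the direction of an edge, which is why the smoothed
trajectory is not used here. Edges whose net dependent integral falls below
`tau` (default 0.05) times the range of the target's independent curve are
dropped; surviving edges carry the sign and absolute area of their
dependent curve. Outgoing hubness of a node sums, over its targets, the
integral of the absolute dependent curve divided by the target's
independent-curve integral; roles are primary hub (only outgoing),
secondary hub (both), and subordinate (no outgoing edges).

Cell-cell networks within one embryo use the identical machinery on the
transposed table (cells as variables, genes ordered by their expression
index as observations); phase labels only annotate the result.

## What the simulator emulates

`simulate_pairwise()` reproduces the paired two-cell-type design: an
ascending index grid drawn uniformly on `[1, 10]`, trajectories solved from
the coupled system, and bivariate AR(1) noise added to the expression
values, after which the niche index is recomputed as the noisy pair sum —
exactly how real data are processed. In the default *consistent-NI* mode
the grid is iterated (damped fixed point, tolerance 1e-8 of the span,
affinely rescaled each step to keep the requested range) until the
noise-free pair sum reproduces the grid, so `N = g1 + g2` holds exactly for
the noise-free data; when strong coupling makes the pair sum non-monotone
no such grid exists and the simulator falls back to the *independent-grid*
mode with a warning, recording which mode produced the data. Default noise
is a 1-5% residual standard deviation with serial correlation 0.3 and
cross-type correlation 0.2 — the regime of averaged expression profiles
rather than raw single-cell counts (count noise is deliberately out of
scope; the observation model is Gaussian).

`simulate_network()` plants an exactly-sparse signed topology and builds
each node as its power curve plus AR(1) fluctuations plus the dependent
integrals of its regulators, where the dependent rates respond to the
regulators' *realized* (fluctuating) series, iterated to a damped fixed
point. This propagation of fluctuations from regulator to target is the
package's own design choice: if noise is added only after solving the
noise-free system, every trajectory is a smooth function of one shared
index and the true topology is information-theoretically unrecoverable —
any smooth curve explains any other. Real regulatory data carry
sample-level covariation, and the generator reproduces that feature.
Simulated expression can occasionally be negative at high noise; file
writers clamp at zero, in-memory analyses use the values as generated.

## Numerical choices

* RK4 sub-stepping: max step = span/100; halving the step size reduces the
  closed-form error at least 8-fold (fourth order).
* Correlations are bounded at `|rho| <= 0.95`. Without the bound the MLE
  can ride a near-singular covariance spike in which smooth lack-of-fit is
  absorbed as almost-perfectly correlated noise.
* Tied index values are separated by a jitter of `1e-9 * range` after a
  stable sort, because the integrator needs strictly increasing grids.
* Units in which a gene is silent in both cell types (`N = 0`) are dropped:
  power laws with negative exponents are undefined at zero.
* Zeros in the log-log initialization of power fits are offset by half the
  smallest positive value; the definitive fit minimizes untransformed SSE,
  so the offset does not bias the estimate.
* EM clustering: k-means initialization on log-log slope/intercept
  features, convergence at `|delta loglik| < 1e-6`, at most 200 iterations,
  5 restarts by default; the M-step profiles the proportionality
  coefficient in closed form and solves the exponent by Brent search, so
  the mixture log-likelihood is monotone. Residuals are independent
  Gaussians within the clustering step (the AR(1) structure is reserved for
  the qdODE likelihoods; clustering is a screening device). The AIC
  parameter count is `K * (2 per curve per group) + K variances + (K - 1)`
  mixing proportions.
* Permutation refits inherit the Legendre order and multi-start settings of
  the observed fit, keeping the null exchangeable. Heavier calibration
  studies use a reduced, but identical-for-all-datasets, optimizer budget;
  a permutation test remains exact under any fixed procedure.

## Study sizes used by the shipped tests

The validation suite runs at desk scale on one CPU: power-law recovery at
n = 50 over 100 seeds; pairwise recovery at n = 15 and 50 over 50 seeds
each; LR calibration over 200 null datasets with 200 permutations each and
power over 50 replicates with 39 permutations; classification over 50
replicates for each of the eleven interaction patterns; one 10-node network
at n = 60; module-count selection over 25 seeds. The acceptance script
recomputes the same quantities at a further reduced size.

## Known limitations

These limits were established on synthetic data during development and are
inherent to the model class rather than to the implementation:

* **Decomposition identifiability.** A two-parameter power curve on a
  one-decade index range approximates almost any smooth monotone curve to
  1-3%; dependent integrals of bounded Legendre rates are exactly such
  curves. The likelihood is therefore close to flat along the
  power-versus-dependent trade-off within each margin: total mean curves
  are recovered accurately, but the magnitude of the dependent component is
  strongly shrunk, and its per-direction sign is only weakly identified.
  The ranked-start rule makes the reported decomposition deterministic, not
  more informative.
* **Direction resolution under the sum constraint.** Because the niche
  index *is* the observed pair sum, the residuals of the two cell types are
  structurally anti-correlated (the fitted `rho12` sits near its bound by
  design, not by error), and effectively only the difference of the two
  dependent components is well determined. Influence of type 2 on type 1
  cannot be sharply separated from influence of type 1 on type 2; estimated
  directed effects tend toward a symmetric split. Likelihood-ratio
  *detection* of interaction is unaffected, but Table-1-style directional
  classification from these data should be read with this caveat.
* **Strong coupling.** The coupled system integrated from a noisily
  observed initial value is exponentially sensitive when dependent rates
  rival the independent rates over a long index span; simulation and
  estimation are only well behaved in the weak-to-moderate coupling regime,
  and the consistent-NI construction requires the pair sum to stay
  monotone.
* **Network support recovery.** Even with fluctuation propagation, shared
  ancestors spread correlated wiggles through the graph, and direct
  influence competes with indirect paths; support recovery degrades as the
  planted graph becomes denser.

Passing simulation tests therefore demonstrate internal consistency of the
machinery and calibrated inference under the generator's assumptions; they
do not certify direction-resolved conclusions on real single-cell data,
where the identifiability caveats above apply with extra model
misspecification on top.

## Configuration and reproducibility

Every stochastic entry point takes an integer seed and is reproducible
bit-for-bit given it. The command-line interface (`qdgame_cli()`, or the
`qdgame` script under `inst/scripts/`) accepts a YAML configuration with
`model` (lop_order, tau, max_predictors), `test` (n_perm, level) and
`optim` (starts, ftol, maxiter) sections, lets flags override the file,
writes a manifest (inputs, seed, parameters, package version) beside every
output, and uses exit codes 0 (success), 2 (input error), 3 (numerical
failure).
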