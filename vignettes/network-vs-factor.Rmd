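---
title: "Comparing network and latent variable models of a covariance matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing network and latent variable models of a covariance matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlatent)
```

## The modeling problem

Given a sample correlation (or covariance) matrix $S$ on $p$ variables and
its sample size $N$, two families of structural accounts compete:

* a **Gaussian graphical model** (GGM), in which edges are partial
  correlations and a missing edge states that two variables are
  conditionally independent given all others:
  $\Sigma = \Delta (I - \Omega)^{-1} \Delta$, with $\Omega$ symmetric,
  zero-diagonal, $|\omega_{ij}| < 1$, zero off the skeleton, and
  $\Delta = \mathrm{diag}(\delta)$, $\delta_i > 0$;
* a **confirmatory factor model**, in one of four topologies: correlated
  first-order factors ($\Sigma = \Lambda\Phi\Lambda' + \Theta$), a
  second-order general factor
  ($\Sigma = \Lambda(\Gamma\Gamma' + \mathrm{diag}(1-\Gamma^2))\Lambda' +
  \Theta$), a bifactor structure ($\Sigma = \Lambda\Lambda' + GG' + \Theta$
  with orthogonal unit-variance factors), or a multi-general-factor
  extension of the bifactor structure.

Both are covariance-structure hypotheses, so both can — and must — be judged
against the *same* observed matrix through the maximum-likelihood
discrepancy
$$F_{ML}(\theta) = \ln|\Sigma(\theta)| - \ln|S| +
  \mathrm{tr}\!\left(S\,\Sigma(\theta)^{-1}\right) - p,$$
which is zero iff $\Sigma(\theta) = S$. $(N-1)\,F_{ML}$ at the minimum is the
model $\chi^2$. Fitting a network to a transformed matrix (for instance
treating a pruned partial-correlation matrix as if it were a correlation
matrix in SEM software) breaks the likelihood and produces uninterpretable
fit statistics; keeping both families inside one $F_{ML}$ framework is the
entire point of the package.

### Assumptions

* Multivariate normality of the underlying data (the discrepancy is the
  Gaussian one; no robust corrections are provided).
* Complete data summarized by $S$ and $N$; no mean structure is modeled.
* Correlation matrices are analyzed as covariance matrices. This mirrors
  common practice with standardization-sample correlation matrices, but it
  ignores the sampling constraint that a correlation matrix has a fixed unit
  diagonal; test statistics are therefore approximate in the same way they
  are in any SEM run on a correlation matrix. **Caveat**: standard errors of
  standardized parameters inherit this approximation.
* Standardized convention throughout: all factor variances are fixed to 1
  (not marker-variable scaling), matching correlation-matrix input and
  standardized loadings. For the second-order model the first-order
  disturbances are derived, $\Psi = 1 - \Gamma^2$, so the first-order factor
  variances stay at 1.

## The workflows

**Pruning.** The saturated partial-correlation matrix is the closed form
$\omega_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$, $K = S^{-1}$.
Each off-diagonal entry is a partial correlation of order $p-2$, tested
two-sidedly with the Fisher-z statistic
$z = \mathrm{atanh}(\omega)\sqrt{N - (p-2) - 3}$ at level $\alpha$
(default **0.01**). Surviving edges form the skeleton; the skeleton is then
refitted confirmatorily. Choices worth stating:

* The default is a *single* calculate-then-prune pass followed by one
  confirmatory refit, because that is the transparent baseline;
  `prune_recursive = TRUE` iterates refit-and-test (Wald statistics from the
  constrained fit) until no edge falls. Reference implementations differ in
  whether and how they iterate, and published reports rarely print the
  recipe, so both are exposed and neither is guessed to be "the" procedure.
* A statistic landing exactly on the critical value *retains* the edge:
  conservative toward the saturated truth.
* The test needs $N > p + 3$; below that the function refuses with the
  minimal usable $N$ rather than returning a statistic with nonpositive
  variance.

**Replication.** `extract_and_confirm(A, B)` prunes on sample A and refits
the fixed skeleton with free parameters on sample B — the network analogue
of configural cross-validation. Variables are matched by label, never by
position; the direction is fixed A→B (run it twice for both directions).

**Comparison.** `compare_models()` fits every supplied model to one sample
and reports $\chi^2$(df), $p$, CFI, TLI, RMSEA with 90% CI, AIC, BIC, plus
qualitative labels (RMSEA ≤ 0.05 good, ≤ 0.08 adequate, ≤ 0.10 mediocre,
else unacceptable; CFI/TLI > 0.97 good, ≥ 0.95 acceptable). Nonidentified
models appear with a refusal note; non-convergent fits appear with a
NON-CONVERGED marker; fabricated indices are never printed. Rows are sorted
by model name so the table is invariant to supply order.

## Identification

A covariance structure is locally identified at $\theta$ iff the Jacobian
$\partial\,\mathrm{vech}\,\Sigma(\theta)/\partial\theta'$ has full column
rank. `check_identification()` evaluates this numerically at (default) 5
random interior parameter points, treating singular values below
$10^{-8}$ of the largest as zero, and takes the maximum rank across points:
rank can only drop on a measure-zero set, so the maximum is the generic
rank. Only *local* identification is checked; no algebraic (global) proof is
attempted.

The check cleanly separates the one-general-factor bifactor structure
(identified) from multi-general-factor structures: with $q$ orthogonal
general factors loading on all indicators, any rotation of the general block
leaves $GG'$ unchanged, so the deficiency is at least $q(q-1)/2$ — for the
four-general-factor "penta" template the measured deficiency is exactly 6.
Consistently, forcing a fit of that template (override flag) converges in
value but leaves the observed information matrix singular: standard errors
are reported as uncomputable with the implicated parameters named, not as
pseudo-inverse numbers. An uncomputable standard error is the classic
symptom by which applied software betrays a nonidentified model.

## Numerical choices

* **Optimizer.** Quasi-Newton (BFGS) on an unconstrained reparameterization:
  $\mathrm{atanh}$ for partial correlations, factor correlations and
  second-order loadings; $\log$ for scaling values and residual variances;
  identity for loadings. Iterates therefore cannot leave the box
  constraints, and residual variances approach 0 only asymptotically
  (Heywood cases land softly on the boundary instead of crossing it). A
  parameter vector whose implied $\Sigma$ loses positive definiteness mid
  line-search receives a large penalty value, which backtracking rejects.
* **Gradients** are analytic for every family, assembled from
  $\partial F/\partial\Sigma = \Sigma^{-1} - \Sigma^{-1}S\Sigma^{-1}$ in
  $O(p^3)$ per gradient regardless of the parameter count; the test suite
  verifies them against central differences.
* **Starts.** The first start is data-informed (the saturated solution
  projected onto the skeleton for GGMs, with a shrink-back if the projection
  leaves the valid region; neutral loading values for factor models); two
  further seeded jittered starts guard against local minima
  (`n_starts = 3`). Convergence is declared when the maximum absolute
  gradient falls below `1e-6` (BFGS is restarted with a fresh Hessian
  approximation up to five times to get there); otherwise the fit reports
  `converged = FALSE`, never a silent success.
* **Saturated GGMs** (complete skeleton) are returned from the closed form
  $\Omega = $ partial correlations of $S$, $\Delta =
  \mathrm{diag}(S^{-1})^{-1/2}$ — no iteration, exact reproduction of $S$.
* **Sign indeterminacy** of factor loadings is resolved after fitting by
  flipping each factor so its largest-magnitude loading is positive.
* **RMSEA CI**: the noncentrality bounds solve
  $P(\chi^2_{df,\lambda} \le \chi^2_{obs}) = (1 \pm level)/2$ by bracketing
  and bisection (`uniroot`, tolerance $10^{-8}$), clamped at 0 when the
  central distribution already exceeds the target. RMSEA is undefined at
  $df = 0$ and returned as `NA` with an explanation, not as 0.
* **Positive-definiteness tolerance** everywhere: smallest eigenvalue
  $> 10^{-10} \times$ largest.
* **AIC/BIC** penalize one consistent $k$ — the covariance-structure
  parameter count — for every family, and include the full Gaussian
  likelihood constant so values are comparable across runs on the same data.
  Published tables sometimes add mean parameters for some families only;
  differences then shift by a family-specific constant while
  $\Delta AIC = \Delta\chi^2 + 2\Delta k$ continues to hold, which is the
  identity the package validates.

## The synthetic-data generator

`random_population()` emulates the data-generating regimes the comparison
logic presupposes. The GGM mechanism draws a skeleton at a given edge
density (default 0.35, a moderately sparse network), weights uniform on
**[0.1, 0.4] and positive by default** — predominantly positive edges are
what produce the positive manifold of correlations observed in cognitive
batteries, and with this regime every population correlation is nonnegative
— and standardizes $\Sigma$ to correlation scale so that generated data
match correlation-matrix inputs. Draws whose $I - \Omega$ is not positive
definite are rejected and redrawn (the acceptance rate at $p = 15$, density
0.35 is a few percent, so the retry cap is generous at 2000). Mixed-sign
weights are a flag away. The factor mechanism builds simple-structure
loadings uniform on [0.5, 0.8] with factor correlations 0.3 and residuals
$1 - $ communality.

`draw_sample_moments()` samples $N$ multivariate normal vectors via the
Cholesky factor and returns their correlation (or covariance) matrix;
everything is reproducible bit-for-bit from the seed.

What the generator does **not** emulate: non-Gaussian margins, ordinal
(polychoric) data, missingness, mean structures, longitudinal dependence.
Passing recovery and calibration tests on these populations therefore shows
the estimator and the pruning test work *under the model's own assumptions*;
it does not certify behavior on real, coarsely scaled test scores.

## Study-sized problems used in the checks

The shipped experiments use sizes chosen to mirror the application domain:
15 variables (a full adult intelligence battery) with discovery/confirmation
sample sizes 1800 and 1112 (standardization-study scale) for the pipeline;
$p \le 3$ problems for brute-force grid-search oracles (iterative zooming
grids, with residual variances gridded on a log scale when an optimum sits
on the $\Theta \to 0$ boundary); a 6-node chain at $N = 5000$ over 100
replications for edge sensitivity; a 10-node empty network at $N = 1000$
over 200 replications for type-I calibration of the pruning test, whose
false-edge rate should sit near $\alpha = 0.01$ within binomial error.

## Shipped WAIS-IV templates

The 15 subtest labels (SI, VC, IN, CO, BD, MR, VP, FW, PC, DS, AR, LN, SS,
CD, CA) and four topologies: `wais_measurement()` (4 correlated index
factors), `wais_hierarchical_g()` (second-order g), `wais_bifactor()`, and
`wais_pentafactor()` (4 group + 4 general orthogonal factors; shipped for
the identification demonstration). Two open points are resolved as options
rather than guesses:

* **FW assignment.** Published diagrams disagree on whether Figure Weights
  sits under the Perceptual or the Working Memory factor. Both variants ship
  (`fw = "perceptual"` is the default, matching the published battery's
  index structure); switching variants changes the pattern matrix, not the
  code path.
* **Cross-loadings.** The published four-factor measurement model carries
  two cross-loadings beyond simple structure (df 82 rather than 84; 84
  rather than 86 for the hierarchical version), but their identity is
  specified in a test manual figure that is not reproduced here. The
  templates default to simple structure and accept a `cross_loadings`
  argument; exact reproduction of the published factor-model rows requires
  supplying the manual's two loadings.

## Known limitations

* Local (numeric) identification only; a model could in principle be
  globally nonidentified yet locally identified at generic points.
* No regularized (lasso) network estimation — the workflow is significance
  pruning, deliberately.
* No ordinal/polychoric input, FIML for missing data, mean structures,
  robust/scaled test statistics, or SRMR.
* Analyzing correlation matrices as covariance matrices is an approximation
  (above); absolute AIC/BIC values depend on the parameter-count convention
  (above).
* The recursive pruning variant uses Wald tests from refitted models; its
  operating characteristics are not separately calibrated in the shipped
  experiments.
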