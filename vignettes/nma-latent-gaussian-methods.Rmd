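---
title: "Network meta-analysis as a latent Gaussian model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network meta-analysis as a latent Gaussian model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmalgm)
```

# The models

`nmalgm` fits contrast-based network meta-analysis (NMA) models with an
*arm-based likelihood*: each trial arm contributes its raw outcome, so no
normal approximation of effect estimates and no continuity correction is
ever needed.  Trial $i$ has arms $k = 1, \dots, K_i$ with treatments
$t_1 < t_2 < \dots$; the lowest-numbered treatment in the trial is its
baseline.  A link function $G$ maps the arm-level parameter to an
additive scale:

$$
G(\theta_{i,t_k}) =
\begin{cases}
\mu_i & k = 1\\
\mu_i + d_{t_1 t_k} + \gamma_{i,t_1 t_k} + \omega^{D(i)}_{t_1 t_k}
  + (x_i - \bar x)\beta & k > 1.
\end{cases}
$$

Three endpoint families are supported: binomial counts with the logit
link, normal arm means with the identity link (the arm standard error
$s/\sqrt{n}$ is treated as known), and Poisson counts with a log link
and an exposure offset.

The terms beyond $\mu_i + d_{t_1 t_k}$ are switched on by the model
kind:

* **fixed**: none of them — a fixed-effect NMA.
* **consistency**: trial-specific heterogeneity effects
  $\boldsymbol\gamma_i \sim N(0, \Sigma_\gamma)$ with the
  compound-symmetric (homogeneous) covariance — diagonal $\tau^2$,
  off-diagonal $\tau^2/2$ — which encodes equal heterogeneity variances
  for every contrast of a multi-arm trial.
* **jackson**: additionally, design-by-treatment interaction effects
  $\boldsymbol\omega^{D} \sim N(0, \Sigma_\omega)$ (diagonal $\kappa^2$,
  off-diagonal $\kappa^2/2$), drawn *once per design* — a design being
  the set of treatments a trial compares — and shared by all trials of
  that design.  $\kappa$ measures global inconsistency; the individual
  $\omega$'s locate it.
* **metareg-consistency / metareg-jackson**: one constant
  covariate-by-treatment interaction $\beta$ relative to the reference
  treatment, entered with the centered covariate $(x_i - \bar x)$.  For
  a contrast between two non-reference treatments the interaction terms
  cancel exactly; the engine's incidence matrix encodes the coefficient
  $(x_i - \bar x)\,[\mathbb 1(t_k \ne \mathrm{ref}) -
  \mathbb 1(t_1 \ne \mathrm{ref})]$, so this cancellation holds by
  construction and is asserted in the test suite.

The network is parametrized through *basic parameters* $d_{1t}$, the
effects of each treatment against a reference (default treatment 1);
every other contrast is the functional combination
$d_{t_1 t_k} = d_{1 t_k} - d_{1 t_1}$.  The Jackson model is invariant
to this choice; we fix lowest-first baselines and reference-based basic
parameters because they make the implementation and the interpretation
uniform.  When a dataset lists arms in another order, the reader sorts
them; the design catalogue likewise identifies a design with the *set*
(not sequence) of its treatments.

## Priors

All fixed-effect-like latent parameters ($\mu$, $d$, $\beta$) get
independent $N(0, 1000)$ priors.  The hyperparameters $\tau$ and
$\kappa$ get uniform priors on the standard-deviation scale, by default
$U[0, 5]$, configurable per fit (e.g. $U[0, 2]$ when outcomes are rare
and the logit scale is compressed).  Internally the engine works on
$\theta = \log \tau^2$ (and $\log \kappa^2$), an unbounded and
better-conditioned scale for optimization; the uniform prior is
transported there with the exact Jacobian $d\sigma/d\theta = \sigma/2$.

## The compound-symmetric decomposition

A vector of contrasts with covariance $\tau^2 I/2 + \tau^2 J/2$ is
represented internally as `shared + idiosyncratic` components,
$\gamma_{i,t_1t_k} = a_i + b_{ik}$ with independent
$a_i, b_{ik} \sim N(0, \tau^2/2)$ (a single component with the full
variance for two-arm trials).  This reproduces the required covariance
exactly (`cs_decompose()` is tested against `cs_covariance()` to
machine precision) and makes the latent prior precision diagonal, which
both engines exploit.  Reported $\gamma$ and $\omega$ marginals are
marginals of the *sums*, obtained through the layout's report map.

# The nested Laplace engine

The latent vector $\alpha = (\mu, d, \beta, \gamma, \omega)$ is
Gaussian given $\Psi = (\tau^2, \kappa^2)$, so the model is a latent
Gaussian model with at most two hyperparameters, and the classic nested
approximation applies:

1. **Gaussian approximation at fixed $\Psi$.**  Damped Newton
   (Fisher-scoring) iterations on $\log p(\alpha \mid \Psi, y)$ until
   the gradient max-norm is below $10^{-8}$ (at most 100 iterations,
   with step halving).  For the normal family one step lands on the
   exact mode and the approximation is exact — the engine is tested to
   agree with a directly computed linear-mixed-model marginal
   likelihood at $10^{-8}$.
2. **Hyperparameter posterior.**  The standard Laplace expression
   $\tilde p(\Psi \mid y) \propto p(y \mid \alpha^*) p(\alpha^* \mid
   \Psi) p(\Psi) / \tilde p_G(\alpha^* \mid \Psi, y)$ evaluated at the
   conditional mode.  Its mode is found by golden-section search (one
   hyperparameter) or Nelder-Mead polished by BFGS (two), with the
   curvature from central finite differences (step $10^{-4}$ on the
   log-variance scale).  If the mode sits on the prior boundary — which
   happens when the data cannot identify a variance, e.g. a saturated
   network — the engine warns that the posterior is prior-dominated and
   floors the curvature so that the exploration still spans the prior
   support.
3. **Exploration.**  Default is an axis-aligned lattice in standardized
   coordinates (step 0.5 posterior sd), expanded until the log density
   drops by more than 6 and capped at 50 steps per direction with a
   warning (flat densities).  A central composite design (center, axial
   and factorial points on a sphere of radius $1.1\sqrt q$, with
   weights solved to integrate a Gaussian's mass and second moments
   exactly) is available to mirror the usual low-cost default; the
   dense grid is the reference in all tests.
4. **Latent marginals.**  Each reported parameter (or any linear
   functional, e.g. a functional contrast) gets a
   mixture-of-Gaussians marginal: the conditional Gaussian marginal at
   each grid point, weighted by the normalized hyper-posterior weights.
   Summaries (mean, sd, equi-tailed quantiles by inverse-CDF
   interpolation) come from the exact mixture; the stored density grid
   is renormalized by its trapezoid integral.  The Gaussian conditional
   is an explicit, testable approximation; the `laplace_marginals`
   option instead recomputes each reported marginal by a per-slot
   constrained Laplace approximation (mode restricted to
   $c^\top\alpha = x$, corrected by the restricted log-determinant),
   which reproduces the Gaussian answer exactly in the normal family
   and shifts logit-scale marginals by a few $10^{-3}$ in the
   applications — hence the cheaper Gaussian conditional is the
   default.
5. **Hyperparameter marginals** are formed on a pivoted-Cholesky
   lattice in which the target coordinate depends on a single lattice
   axis, so marginalization is a sum over the other axis; the result is
   interpolated and transformed to the standard-deviation scale with
   the exact Jacobian.

## DIC

The deviance is the full $-2\log p(y \mid \alpha)$, normalizing
constants included, for all three families; this is the convention
under which the dichotomous applications' published values are
reproduced, and it keeps model comparisons on one scale.  $\bar D$ is
estimated from draws of the mixture approximation with an importance
correction: draws from each grid point's Gaussian are reweighted by the
exact latent posterior over the Gaussian proposal (self-normalized per
point).  The correction is exact in the normal family (unit weights)
and removes the upward bias a purely Gaussian conditional leaves in
$E[D]$ for binomial likelihoods (about 1.5 deviance units in the
smoking application).  $\hat D$ is the deviance at the importance-
corrected posterior mean of $\alpha$, $p_D = \bar D - \hat D$,
$\mathrm{DIC} = \bar D + p_D$.  The sampler uses a fixed internal seed
(20180116, overridable), so a repeated fit is bit-identical; with the
default 4000 target draws the residual Monte-Carlo wobble in DIC is a
few tenths of a unit.

# The MCMC cross-check

`sample_posterior()` is a from-scratch Metropolis-within-Gibbs sampler
over exactly the same latent parametrization: scalar random-walk
updates for every latent component with incremental linear-predictor
bookkeeping (C++ kernel), and log-sd random walks for $\tau$ and
$\kappa$ whose uniform-on-sd priors contribute the Jacobian $e^{u}$.
Sampling the decomposed shared/idiosyncratic components rather than the
correlated $\gamma/\omega$ vectors is equivalent by construction and
keeps every full conditional univariate.  Step sizes adapt toward
roughly 35% acceptance in batches of 50 during burn-in only, so
detailed balance holds for retained draws.  Defaults (3 chains, burn-in
30000, 50000 post-burn-in iterations for Jackson kinds and 20000
otherwise, thinning 5) match common practice for these applications;
the inconsistency sd mixes slowly, and the batch-means Monte-Carlo
standard errors (20 long batches, reported for the mean and the median)
should be consulted before quoting its median.  Gelman-Rubin statistics
are provided for multi-chain runs.

# The synthetic-data generator

`simulate_network()` draws from the generative model itself: baselines
$\mu_i \sim N(0, 1)$ (the baselines are nuisance parameters; any
dispersed choice works and the sd is configurable), heterogeneity
contrasts per trial from the compound-symmetric covariance,
inconsistency contrasts drawn once per design and shared by its trials
(this design-sharing is asserted in tests), and outcomes from the
chosen family with per-arm size $n = 100$ by default — large enough to
keep desk-scale fits identified.  A truth record accompanies every
draw for recovery tests.

What the generator deliberately does *not* emulate: arms with zero or
near-zero events (the sparse-data regime where any vague-prior Bayesian
GLMM, whatever the inference engine, is biased), unequal and extreme
arm sizes, covariates correlated with design membership (confounding),
or non-normal random effects.  A passing property suite therefore
certifies the inference machinery on well-identified networks, not
robustness to those real-data pathologies.

# Numerical choices and test problem sizes

* Latent gradient tolerance $10^{-8}$; hyper-optimizer tolerance
  $\sim 10^{-7}$ on the log density; finite-difference step $10^{-4}$.
* Grid step 0.5 sd, drop cutoff 6; hyper-marginal lattice step 0.4,
  cutoff 8.
* Equi-tailed intervals by inverse-CDF interpolation on the density
  grid.
* Ties in design enumeration cannot arise (set identity); design ids
  follow first appearance in the data.
* Degenerate inputs: one-arm trials, duplicated treatments, events
  exceeding sample sizes and in-trial covariate variation are rejected
  with row-level messages; a disconnected network is a warning, since
  within-component contrasts remain estimable.

The test suite exercises the engines at deliberately desk-scale sizes —
six-trial networks for the MCMC-against-Laplace comparisons, fifty
four-trial replicates for interval coverage, and the 24-trial smoking
network for the published-value checks — sizes at which the full suite
completes in a few minutes while every code path (multi-arm trials,
multi-trial designs, both hyperparameters, covariates) is exercised.

# Known limitations

* No treatment-ranking probabilities: the deterministic engine produces
  marginal, not joint, posteriors.
* No loop-inconsistency (Lu-Ades) model and no node splitting; the
  design-by-treatment interaction model subsumes the former for our
  purposes.
* Only the constant covariate-interaction model; exchangeable or
  unrelated interaction coefficients are out of scope.
* The normal family models arm means with known standard errors; it
  does not estimate arm-level sampling variances.
* Gaussian conditional marginals can be slightly narrow for very sparse
  binomial data; the `laplace_marginals` option and the MCMC engine are
  the built-in checks.
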