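---
title: "Evidence maximisation by EM under a general Gaussian weight prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence maximisation by EM under a general Gaussian weight prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggwpem)
```

## The model and its objective

`ggwpem` fits Gaussian linear basis-function regression

$$t_n = \omega^\top \psi(x_n) + \varepsilon_n, \qquad
\varepsilon_n \sim N(0, \lambda^{-1}),$$

under the *general Gaussian weight prior* (GGWP): each weight has its own
precision $\eta_i$ **and** its own mean $\mu_i$,

$$p(\omega \mid \eta, \mu) = \prod_{i=1}^M N(\omega_i \mid \mu_i, \eta_i^{-1}).$$

The zero-mean special case $\mu = 0$ is the automatic-relevance prior of
the relevance vector machine and is available as `mu_mode = "fixed_zero"`.
All hyperparameters $(\eta, \lambda, \mu)$ are estimated by type-II
maximum likelihood: maximising the *evidence* (marginal likelihood)

$$\ln p(T \mid X, \eta, \lambda, \mu)
 = \tfrac{N}{2}\ln\lambda - G(m) + \tfrac12\sum_i\ln\eta_i
 + \tfrac12\ln|C| - \tfrac{N}{2}\ln 2\pi,$$

with posterior moments $m = C(\Lambda\mu + \lambda\Psi^\top T)$,
$C = (\Lambda + \lambda\Psi^\top\Psi)^{-1}$ and
$G(m) = \tfrac{\lambda}{2}\lVert T-\Psi m\rVert^2
+ \tfrac12 (m-\mu)^\top\Lambda(m-\mu)$.

Treating the weights as latent variables gives the EM view: the E step
computes $(m, C)$ — the variational distribution that zeroes the KL
divergence to the exact posterior — and the M step maximises the lower
bound over the hyperparameters, yielding

$$\eta_i \leftarrow \frac{1}{m_i^2 + C_{ii}}, \qquad
\lambda \leftarrow \frac{N}{\lVert T-\Psi m\rVert^2
  + \operatorname{Tr}(\Psi^\top\Psi C)}, \qquad
\mu \leftarrow m.$$

## The two M-step variants

The default variant, `as_printed`, applies the three updates above
simultaneously from the same E-step moments.  A subtlety matters here:
with a *free* $\mu$, the bound's exact maximiser in $\eta_i$ is centred,
$1/((m_i-\mu_i)^2 + C_{ii})$, not $1/(m_i^2 + C_{ii})$.  The simultaneous
uncentred update is therefore **not** an ascent step in $\eta$ once
$\mu \ne 0$, and the evidence trace can decrease transiently.  We keep it
as the default because it is the method's canonical form, and we expose
the consequences rather than hiding them:

* `update_variant = "centered_sequential"` performs coordinate ascent —
  $\eta$ updated with $\mu$ held at its old value, then $\mu \leftarrow m$,
  then $\lambda$ — each sub-step maximising the bound, so the evidence
  trace is non-decreasing (asserted in the tests to $10^{-8}$ slack).
* With `mu_mode = "fixed_zero"` the centring reference is $0$ and the two
  variants coincide bitwise.

A related identifiability fact shapes everything downstream: with $\mu$
free, the evidence approaches its supremum only as $\eta \to \infty$ with
$\mu$ at the no-prior (least-squares-like) solution — the prior collapses
onto the posterior mean and the evidence tends to the plug-in likelihood
from below.  The EM fixed point $\eta_i = 1/(m_i^2 + C_{ii})$ sits away
from that supremum, while box-constrained direct optimisers (the PSO
baseline) crawl along the ridge indefinitely.  This is also why
precisions are capped (`eta_cap = 1e12`): unbounded growth of single
$\eta_i$ entries is what drives the posterior precision towards numerical
singularity.

## Convergence monitoring, and what "fast convergence" means

Hyperparameter convergence is awkward to detect directly, so the loop
monitors the objective: it stops when $|\Delta \ln L| <$ `tol` (default
$10^{-6}$) between successive cycles, with `max_iter = 1000`.  Two
behaviours of this rule deserve honesty:

* On typical synthetic problems (see below) the evidence rises steeply
  for the first handful of iterations — the trace *looks* converged after
  about ten — but $|\Delta \ln L|$ then decays very slowly (roughly like
  $1/k$ along weakly identified basis directions), so the $10^{-6}$
  criterion is usually met only after several hundred to a few thousand
  iterations at $M = 10$.  Slow terminal convergence of EM-style
  automatic-relevance updates is a well-known phenomenon; it disappears
  for small, well-conditioned bases ($M \le 4$ converges in roughly ten
  iterations).
* Because the `as_printed` trace can oscillate, an absolute-change rule
  can stop at a sign change of $\Delta \ln L$ while the iteration is
  still moving ("false convergence").  Fixed-point self-consistency
  checks in the test suite therefore run with `tol = 1e-8`, where the
  stopping point is a genuine fixed point; at the default tolerance the
  re-estimation equations are satisfied only to about the stopping
  accuracy, which is what one should expect.

At a converged fixed point the evidence is stationary in $\mu$ (its
gradient is $\Lambda(m - \mu)$) and in $\lambda$; it is *not* stationary
in $\eta$ for the uncentred update — the tests verify the first two by
central finite differences and deliberately do not assert the third.

## Singularity policy

The posterior precision $\Lambda + \lambda\Psi^\top\Psi$ is factorised by
Cholesky.  When its reciprocal condition estimate falls below $10^{-12}$
the covariance is computed by Moore–Penrose pseudo-inverse (log
determinant from a floored symmetric eigendecomposition), flagged, and —
under the default `singular_action = "restart"` — the run is abandoned
and restarted from freshly drawn hyperparameters (seed $+ r$ on restart
$r$, all logged), up to `max_restarts = 20` times before the
pseudo-inverse path is accepted with a `degenerate`/flagged status.
Pseudo-inverse evidence values are imprecise and can break the increase
of the likelihood; they are never silently mixed into converged results.

## The synthetic protocol

`generate_synthetic()` draws data with exactly the structure the model
assumes, so parameter recovery is meaningful end to end: inputs uniform
on $[-1, 1]^d$ (default $d = 1$); a Gaussian-RBF basis with bias,
centers at the first $M - 1$ input points and width equal to the median
pairwise input distance (both resolvable from data, both configurable);
ground-truth hyperparameters drawn as in `initialize_hyperparameters()`
($\ln\eta_i$ uniform on $[\ln 10^{-3}, \ln 10^{3}]$, $\ln\lambda$ uniform
on $[\ln 10^{-2}, \ln 10^{2}]$, $\mu_i$ standard normal); then
$\omega_i \sim N(\mu_i, \eta_i^{-1})$, $\varepsilon \sim N(0,
\lambda^{-1})$, $T = \Psi\omega + \varepsilon$.  The default study size
is $N = 100$, $M = 10$.  Sizes, ranges and the basis are implementation
choices (documented here, not external facts); everything is reproducible
bitwise from a single integer seed, and the ground truth travels with the
dataset.

What the generator does *not* emulate: model misspecification.  Real data
have heteroscedastic noise, non-Gaussian weights and basis mismatch;
passing recovery tests on this generator shows correctness of the
machinery under the model's own assumptions, not robustness beyond them.

## The PSO baseline

`pso_fit()` maximises the same log evidence with a textbook global-best
particle swarm over $(\ln\eta, \ln\lambda, \mu)$ — precisions searched in
log space to respect positivity.  Defaults: 30 particles, inertia 0.72,
cognitive = social = 1.49, velocity clamp 20 % of the box width, bounds
$\ln\eta \in [-7, 28]$ (keeping $\eta$ at or below the EM cap),
$\ln\lambda \in [-7, 7]$, $\mu \in [-10, 10]$ — canonical
constriction-like settings, since no principled problem-specific values
exist.  To compare convergence with EM on one criterion, the swarm counts
as converged at the first iteration where the global-best improvement has
stayed below the EM tolerance for 50 consecutive iterations (the patience
window guards against the trivial zero-improvement iterations of a
monotone best-so-far trace).  On the default synthetic problem the swarm
typically keeps finding $> 10^{-6}$ improvements along the
$\eta$-ridge for the whole 10,000-iteration budget, though collapsed
swarms that stall permanently do occur on some seeds — the outcome is
genuinely seed-dependent.  EM seeded *at* the swarm's best point (using
the monotone variant) can only improve it, which the tests assert.

## Numerical choices

* Gram quantities $\Psi^\top\Psi$, $\Psi^\top T$, $T^\top T$ are
  precomputed once per dataset; every posterior/evidence evaluation is
  then $O(M^3)$ independent of $N$ (the swarm makes $3\times10^5$ of
  them).
* Linear solves use the Cholesky factor of the precision; the covariance
  is materialised explicitly because the updates need $C_{ii}$ and
  $\operatorname{Tr}(\Psi^\top\Psi C)$, and is symmetrised as
  $(C + C^\top)/2$.
* $\ln|C|$ is the negated log determinant of the precision from its
  Cholesky diagonal; on the pseudo-inverse path, from symmetric
  eigenvalues floored at $10^{-300}$.
* The raw product form of the evidence exists only for cross-checks; all
  routine computation is in log space.
* Degenerate M-step inputs ($m_i^2 + C_{ii} = 0$, or zero expected
  residual) raise errors rather than producing infinite precisions.
* $N < M$ is permitted (the precision is still positive definite in
  exact arithmetic) with a warning.

## Test problem sizes

The suite exercises the full study size ($N = 100$, $M = 10$) where the
claim under test concerns the optimisation dynamics, and small instances
($M \le 4$, $N \le 30$) where an independent oracle provides the expected
value: adaptive quadrature and tensor-grid Gauss–Legendre quadrature for
the evidence at $M \in \{1, 2\}$, QR least squares for the
$\eta \to 0$ posterior limit, BFGS-plus-numerical-Hessian for the general
conjugate posterior, $10^5$-draw Monte Carlo for the predictive moments,
and $10^4$ replicate draws for the generator's weight moments.  The noise
precision recovery study uses $N = 500$, $M = 5$, true $\lambda = 25$
over 20 seeds in the zero-mean mode.

## Known limitations

* The uncentred simultaneous update is faithful to the method's canonical
  form but is not an ascent method with free $\mu$; use
  `centered_sequential` when a monotone trace matters.
* With free $\mu$ the evidence has no interior maximum in $\eta$
  (identifiability ridge); reported $\hat\eta$ values should be read as
  fixed points of the update law, not as maximum-evidence estimates.
* Absolute-change stopping can fire on oscillation sign changes at loose
  tolerances.
* Basis pruning (sparsification), hyperpriors over $(\eta, \lambda, \mu)$,
  non-Gaussian likelihoods and multi-output regression are out of scope.
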