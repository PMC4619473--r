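---
title: "Optimal Bayesian risk classification and risk estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal Bayesian risk classification and risk estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obrisk)
```

## The problem

Small-sample classification — the regime of most genomic and biomedical
studies — makes risk estimation at least as hard as classification itself.
Distribution-free resampling estimators (cross-validation, leave-one-out, the
0.632 bootstrap) are nearly unbiased but so variable at small $n$ that a
reported error rate can be almost uninformative, and distribution-free RMS
guarantees are vacuous: `distribution_free_rms_bound(n)` shows that for a
leave-one-out estimate of a discrete histogram rule, no sample below a couple
of hundred points guarantees an RMS under 0.5.

`obrisk` takes the Bayesian route. The unknown feature-label distribution is
assumed to lie in a parameterized uncertainty class: class probabilities
$\mathbf c$ with a prior (known, fixed, or Dirichlet), and class-conditional
parameters $\theta_y$ with conjugate priors. After observing a sample $S$ the
priors become posteriors, and three tools follow:

* the **Bayesian risk estimator (BRE)** $\widehat R(\psi, S) = \mathrm E[R(\psi,
  \mathbf C, \Theta) \mid S]$, the MMSE estimate of the expected risk of any
  classifier $\psi$ under any loss matrix $\lambda(i, y)$;
* the **sample-conditioned MSE** $\mathrm{Var}(R \mid S)$, which says how far
  the true risk can plausibly be from the estimate *for the sample in hand*,
  and extends to arbitrary risk estimators via
  $\mathrm{MSE}(\widehat R_\bullet \mid S) = \mathrm{MSE}(\widehat R \mid S) +
  (\widehat R - \widehat R_\bullet)^2$;
* the **optimal Bayesian risk classifier (OBRC)**, the classifier minimizing
  the BRE, computed pointwise as
  $\arg\min_i \sum_y \lambda(i, y)\, \mathrm E[C_y \mid S]\, f(x \mid y, S)$.

The object that makes all three computable is the **effective density**
$f(x \mid y, S) = \mathrm E[f(x \mid y, \Theta_y) \mid S]$: the posterior
predictive class-conditional density, which plays the role the true density
plays in classical Bayes decision theory. Second moments of the
misclassification probabilities additionally need the **effective joint
density** $f(x, w \mid y, z, S)$ of two points.

## Models with closed forms

**Discrete (histogram) model.** Bins $1..b$ with Dirichlet priors per class.
The effective density is the posterior-mean histogram
$\alpha^{y*}_x / \alpha^{y*}_+$; the joint is
$\alpha^{y*}_x(\alpha^{y*}_w + \delta_{xw}) / (\alpha^{y*}_+(\alpha^{y*}_+ +
1))$; every quantity, including cross moments for any classifier, is a finite
sum (`eps_hat`, `cross_moment_table`, `mse_bre` with `method = "closed"`).

**Gaussian models.** Five covariance structures share one update path
(`update_gaussian`):

| structure | coupling | effective density |
|---|---|---|
| known $\Sigma_y$ | (means independent) | $N\!\big(m^*_y, \tfrac{\nu^*+1}{\nu^*}\Sigma_y\big)$ |
| arbitrary | independent | $t_k$, $k = \kappa^*_y - D + 1$, scale $\tfrac{\nu^*+1}{k\nu^*} S^*_y$ |
| arbitrary | homoscedastic | same with shared $(\kappa^*, S^*)$ |
| scaled identity | independent | $t_k$, $k = (\kappa^*_y + D + 1)D - 2$, scale $\tfrac{\nu^*+1}{k\nu^*}\mathrm{tr}(S^*_y) I_D$ |
| scaled identity | homoscedastic | same with shared $(\kappa^*, S^*)$ |

Hyperparameter containers accept improper priors ($\nu = 0$, small or negative
$\kappa$); propriety is enforced at the point a posterior quantity is
requested ($\nu^* > 0$; $\kappa^* > D - 1$ and $S^* \succ 0$ for arbitrary;
$(\kappa^* + D + 1)D > 2$ for scaled identity), and violations raise errors
naming the offending hyperparameter rather than returning NaN.

For **binary linear classifiers** $g(x) = a'x + b$, the signed margin
$(-1)^i g(X)$ under a Student-t effective density is a non-standardized
univariate t, so $\widehat\varepsilon^{i,y}$ is a regularized incomplete beta
expression (`t_cdf_at_zero`), and the pair $((-1)^i g(X), (-1)^j g(W))$ under
the effective joint density is bivariate t, so the cross moments
$\mathrm E[\varepsilon^{i,y}\varepsilon^{j,z} \mid S]$ are bivariate t CDFs at
the origin with correlation $(-1)^{i+j}/(\nu^*_y + 1)$ when $y = z$, and
correlation 0 — but a *shared* mixing variable — for homoscedastic $y \ne z$.
With known covariance the same expressions use the bivariate normal CDF, and
with independent coupling the $y \ne z$ moments factorize exactly.

### A point about the joint predictive

For scaled-identity models the stacked pair $(x, w)$ is a single elliptical
multivariate t (the package proves this to itself in tests by checking
$f(x)\,f(w \mid x) = f(x, w)$ pointwise to $10^{-8}$). For **arbitrary**
covariance models the two-point predictive is matrix-variate t, whose stacked
vector is *not* multivariate t when $D > 1$. `effective_joint` therefore
returns a marginal-times-conditional representation there, sampled exactly by
drawing $x$ from the effective density and $w$ from the effective conditional
(a single-point posterior update, `effective_conditional`); its rank-1
conditional scale $S^* + \tfrac{\nu^*}{\nu^*+1}(x - m^*)(x - m^*)'$ is sampled
through a non-square matrix square root, so the sampler stays vectorized. The
1-D projections used by the closed forms are unaffected: projections of a
matrix-t are bivariate t.

A related numerical fact: a bivariate t with zero correlation does **not**
factorize into two independent t's — the shared mixing variable still couples
the components, which is exactly why the homoscedastic $y \ne z$ cross moment
differs from the product $\widehat\varepsilon^{i,y}\widehat\varepsilon^{j,z}$.
Tests assert the correct behaviour (agreement with 2-D quadrature of the
joint density, factorization only in the $d \to \infty$ limit).

## Monte Carlo paths

When no closed form applies (multi-class or nonlinear classification under
Gaussian models), `eps_hat` samples the effective density and tabulates
assignment proportions, and `mse_bre` estimates all second moments from
effective-joint pair draws. Two choices matter for variance:

* **one coherent draw set**: $\widehat\varepsilon$, the BRE and the
  cross-moment tables are computed from the same pairs, so the factorized
  part of $\mathrm E[R^2]$ cancels exactly against $\widehat R{}^2$ and the
  remaining $y = z$ terms are empirical covariances. Estimating the terms
  from independent draw sets (the naive composition of `bre` plus
  `cross_moment_table`) needs roughly two orders of magnitude more draws for
  the same MSE accuracy;
* **single shared mixing variable** per joint draw — a joint t is one
  elliptical law, not two independent t's.

Monte Carlo MSE estimates of a nonnegative variance can still come out
slightly negative from noise; they are clamped to zero (with a warning in the
closed-form path, where only float cancellation at the $10^{-10}$ level is
expected).

Default MC sizes follow the full-scale study design ($10^6$ draws per class
and per $(y, z)$ pair); tests and the simulation harness scale them down
(stated below) since the estimates enter as noisy-but-unbiased measurements
with tolerances set from their own standard errors.

## Classifiers and classical estimators

`bdr_classifier` (known parameters), `obrc_classifier`, and the plug-in
baselines `plugin_lda` / `plugin_qda` all share the discriminant
$\arg\min_i \sum_y \lambda(i, y) w_y f_y(x)$, evaluated on the log scale with
a per-point rescaling so that $D = 20$ problems do not underflow; exact ties
go to the lowest class index. Under non-informative-like priors the OBRC
boundary is linear for equal-$\nu^*$ homoscedastic models (a regression test
verifies the hyperplane algebraically) and QDA-like for independent models.

`classical_risk_estimate` implements stratified $k$-fold CV averaged over
repeated partitions (fold remainders dealt round-robin), leave-one-out, and
the 0.632 bootstrap ($0.632 \cdot$ out-of-bag $+\ 0.368 \cdot$
resubstitution). Surrogate training sets on which a rule fails — a singular
QDA covariance at tiny $n$, an empty out-of-bag set — are thrown out and
counted in the `n_failed` attribute; inside resampling the OBRC retrains the
posterior on each surrogate sample with the prior unchanged.

## The synthetic study generator

`sim_model_spec` / `preset_model` define the prior-sampled study conditions:
equal class probabilities, stratified samples with exactly $n/M$ points per
class ($n$ not divisible by $M$ is rejected rather than silently unbalanced),
and Gaussian parameters drawn from the prior (inverse-Wishart covariances —
one shared draw under homoscedastic coupling — then means given covariance).
The eight presets cover $D = 2$ and $D = 20$, $M = 2$ and $M = 5$, arbitrary
and scaled-identity structures, an asymmetric binary loss
$\lambda(0,1) = 2, \lambda(1,0) = 1$ and zero-one loss, with $\nu$ patterns
mixing one informative class ($\nu = 12$) with vague ones ($\nu = 2$).

The covariance scale is parameterized through the *expected* covariance
$\mathrm E[\Sigma] = 0.3\, I_D$: with $k$ the effective prior-predictive
degrees of freedom ($k = 5$ in all presets), the arbitrary models set
$S = 0.3 (k - 2) I_D$ (inverse-Wishart mean $S / (\kappa - D - 1)$) and the
scaled-identity models set $\mathrm{tr}(S) = 0.3 (k - 2)$ (inverse-gamma mean
$\mathrm{tr}(S) / ((\kappa + D + 1) D - 4)$). Holding $\mathrm E[\Sigma]$
fixed across structures is the design choice: specifying the matrix $S$
itself identically across structures would make the scaled-identity
populations twenty times noisier at $D = 20$ and the presets incomparable.

What the generator emulates: prior-matched populations, so optimality
statements (OBRC minimizes mean risk; the BRE minimizes RMS; $Z = (\widehat R
- R)/\mathrm{RMS}(\widehat R \mid S)$ has zero mean and unit variance) hold
*within the model* and tests verify calibrated machinery, not real-data
performance. What it does not emulate: model mismatch (non-Gaussian classes,
prior-population disagreement), feature selection and its selection bias, and
correlated features beyond what the inverse-Wishart induces. Passing tests
therefore demonstrate correctness of the estimators and classifiers, not a
guarantee on any particular dataset; `calibrate_prior_moments` exists
precisely because real-data performance hinges on the prior.

## Numerical choices

* `bvn_cdf`: single-integral reduction along the correlation path,
  96-node Gauss-Legendre; machine-precision in practice (validated against
  iterated adaptive quadrature).
* `bvt_cdf`: adaptive integration of `bvn_cdf` over the chi-square mixing
  variable, restricted to the central $1 - 2\times 10^{-15}$ probability mass;
  observed accuracy $\sim 10^{-8}$, stable from $d$ near zero to the normal
  limit.
* Student-t CDFs at zero go through `pbeta` (regularized incomplete beta);
  all density evaluations are done in log space with `lgamma` normalizers and
  Cholesky quadratic forms.
* Scale matrices are symmetrized after every update; positive definiteness is
  checked by a trace-relative smallest-eigenvalue tolerance ($10^{-10}$).
* Calibration trimming discards the top `ceiling(0.1 * count)` items — the
  conservative reading of "10 %" at non-divisible counts.
* Degenerate points where every weighted density underflows are classified by
  the dominant raw log density; labels are never NaN.

## Problem sizes used by the tests and acceptance script

The acceptance script reruns the five-class study (preset 3) at $n = 10$ with
2,000 replicates and 2,000-point stratified test samples — about 20 s — and
reports the mean and standard deviation of the OBRC true risk. The test suite
runs the same study; standardized-$Z$ calibration under preset 1 at $n = 20$
with 2,000 replicates, $3 \times 10^4$ effective-density draws per estimate
and 6,000-point test samples; closed-versus-MC equivalence over a battery of
20 random linear classifiers at $10^6$ draws per model (draws shared across
the battery); and a $10^6$-draw brute-force check of the discrete closed
forms. Tolerances are three Monte Carlo standard errors of the quantity being
checked (plus the rounding slack of the reference values where those are
printed to two decimals).

## Known limitations

* Closed-form BRE/MSE cover discrete models and binary linear classification
  under Gaussian models; everything else is Monte Carlo (this mirrors the
  scope of the underlying theory).
* The class-probability and class-conditional posteriors must be independent
  — true for the sampling designs implemented here (known, separate, random
  with Dirichlet) but not for, e.g., informative label-dependent censoring.
* Non-conjugate models (e.g. count models for sequencing data) and MCMC
  posterior approximation are out of scope.
* `true_risk` closed forms cover Gaussian binary linear and discrete
  classifiers; other cases use stratified test sampling with the stated
  $1/\sqrt{4 n_{\text{test}}}$ RMS bound.
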