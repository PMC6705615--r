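---
title: "Doubly robust learning of individualized treatment rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust learning of individualized treatment rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlitr)
```

## The problem

An individualized treatment rule (ITR) is a map $d$ from a patient's
baseline covariates $x \in \mathbb{R}^p$ to a recommended treatment
$d(x) \in \{-1, +1\}$. Given observational data
$\{(X_i, A_i, Y_i)\}_{i=1}^n$ — covariates, assigned treatment, and an
outcome coded so larger is better — we want the rule maximizing the
*value* $V(d) = E\{Y(d)\}$, the mean outcome if the whole population were
treated according to $d$. Under ignorability, consistency and positivity,
$V(d) = E[Q\{X, d(X)\}]$ with $Q(x, a) = E(Y \mid X = x, A = a)$, and the
unrestricted optimum is $d^*(x) = \arg\max_a Q(x, a)$.

Regression-based (indirect) estimation fits $\widehat{Q}$ and inverts it;
the postulated outcome model then dictates both the rule class and the
consistency of the estimate. Direct estimation instead maximizes an
estimator of $V(d)$ over a user-chosen rule class. This package implements
the doubly robust direct approach: maximize a convex relaxation of the
augmented inverse probability weighted (AIPW) value estimator
$$
\widehat{V}_{\mathrm{AIPWE}}(d) = \mathbb{P}_n\!\left[
\frac{Y\,I\{A = d(X)\}}{\widehat{\pi}\{d(X); X\}}
- \frac{I\{A = d(X)\} - \widehat{\pi}\{d(X); X\}}{\widehat{\pi}\{d(X); X\}}
\,\widehat{Q}\{X, d(X)\}\right],
$$
which is consistent for $V(d)$ whenever *either* the propensity model
$\widehat{\pi}$ or the outcome model $\widehat{Q}$ converges to the truth.

## From value maximization to weighted classification

Writing $d(x) = \mathrm{sgn}\{f(x)\}$ (with $\mathrm{sgn}(0) = +1$
throughout the package), maximizing $\widehat{V}_{\mathrm{AIPWE}}$ is
equivalent to minimizing a weighted misclassification rate with
per-subject, per-arm weights
$$
\widehat{W}_a = \frac{Y\,I(A = a)}{\widehat{\pi}(a; X)}
- \frac{I(A = a) - \widehat{\pi}(a; X)}{\widehat{\pi}(a; X)}\,
\widehat{Q}(X, a), \qquad a \in \{-1, +1\}.
$$
The class label for arm $a$ is $\mathrm{sgn}(\widehat{W}_a)\,a$ and the
weight is $|\widehat{W}_a|$ (`aipw_weights()`,
`weighted_zero_one_risk()`). Replacing the indicator with a convex
surrogate $\phi$ gives the estimator fitted by `earl()`:
$$
\widehat{f} = \arg\min_f\;
\mathbb{P}_n\!\left[|\widehat{W}_1|\,
\phi\{\mathrm{sgn}(\widehat{W}_1) f(X)\} + |\widehat{W}_{-1}|\,
\phi\{-\mathrm{sgn}(\widehat{W}_{-1}) f(X)\}\right]
+ \lambda \lVert\beta\rVert^2,
$$
over linear rules $f(x) = \beta_0 + x^\top\beta$. Outcome weighted
learning (`owl()`) is the special case $\widehat{Q} \equiv 0$ with hinge
loss: pure inverse probability weighting.

Four surrogates are provided (`surrogate_loss()`): hinge
$\max(1 - t, 0)$, squared hinge, logistic $\log(1 + e^{-t})$, and
exponential $e^{-t}$. Each carries its $\psi$ transform relating excess
surrogate risk to excess value; $\psi$ is invertible on $[0, 1]$ and the
hinge transform ($\psi(\theta) = |\theta|$) yields the tightest value
bound. We evaluate the logistic loss with the natural logarithm exactly as
printed even though then $\phi(0) = \log 2 \ne 1$; a base change would
only rescale the objective and is absorbed by the $\lambda$ grid.

## Tunable parameters

* **`lambda`** (ridge penalty on $\beta$; intercept unpenalized, the
  standard offset convention). Default: selected from the grid
  $2^{-5}, \dots, 2^{5}$ by 10-fold cross-validation of the *normalized*
  IPW value of the held-out recommendations. The normalized (Hajek) form
  is used because it is invariant to weight rescaling and needs no outcome
  model on held-out data; exact ties break toward the larger penalty (the
  simpler rule). Folds in which no held-out subject is concordant with the
  fitted rule are dropped from the CV mean.
* **`clip`** (propensity clipping, default `(0.01, 0.99)`): enforces
  positivity in the weights. The lower bound is deliberately below the
  scenario-3 truth of 0.025 so that a severely imbalanced design remains
  representable.
* **`K`** (`earl_split()`, default 2): number of sample-splitting folds.
  The nuisance models are fit on the *small* fold $I_k$ and the rule on
  its complement $I_{(-k)}$ — note this is the reverse of some
  cross-fitting conventions — and the $K$ linear rules are averaged
  coefficient-wise, which stays inside the linear class. The reported
  aggregated value is the mean over folds of the AIPW value of each fold's
  rule on $I_{(-k)}$ under that fold's nuisances: the surrogate-risk
  aggregate suggested by the theory is not on the outcome scale, so the
  package reports a value-scale quantity and records the choice here.
* **`ridge`** (propensity regularization, default 0): small positive
  values (e.g. `1e-4`, standardized features, intercept unpenalized) guard
  against separation in applications with rare treatment; the strength is
  a user knob because no canonical value exists.

## Numerical choices

The surrogate objective is convex; `minimize_earl()` starts from the zero
rule and uses BFGS with analytic gradients for the smooth losses,
reporting the gradient norm at the solution as an optimality certificate.
The hinge loss is optimized by smoothing continuation — a Huber-smoothed
hinge whose smoothing parameter decreases along
$0.5, 0.05, 0.005, 10^{-4}$ with warm starts — and is certified against a
dense grid-search oracle in the test suite. The logistic loss is computed
through the softplus identity and the exponential loss is capped at
$e^{40}$ (with a warning) so early iterations cannot overflow. Zero
decision values are treated as $+1$ recommendations everywhere, matching
the $\mathrm{sgn}(0) = +1$ convention; the logistic $\psi$ uses
$0 \log 0 = 0$ and its inverse is found by bisection to $10^{-10}$.
Stabilized weights ($SW_a = W_a \,/\, \{I(A=a)/\pi\}$) divide by zero for
subjects observed off-arm; the package sets those entries to zero and
flags the object, since the defining formula is silent there.

## The synthetic benchmark

`simulate_scenario()` draws $X_j \sim$ iid $N(0,1)$ ($p = 10$), assigns
treatment by $\mathrm{logit}\,P(A = 1 \mid X) = \ell(X)$ with
$\ell(x) = x_1 + x_2 + x_1 x_2$ (scenario 1) or $0.5 x_1 - 0.5$
(scenario 2), or fixes $P(A = 1 \mid X) = 0.025$ (scenario 3), and sets
$Y = \sum_j X_j^2 + \sum_j X_j + A\,c(X) + \varepsilon$,
$\varepsilon \sim N(0, 1)$, with contrast $c(x) = x_1 + x_2 - 0.1$. The
truth is fully known: $d^*(x) = \mathrm{sgn}\{c(x)\}$ and
$V^* = p + E|c(X)| \approx 11.131$ in closed form (`optimal_value()`).
`true_value()` scores any rule by averaging the true Q-function over
fresh covariate draws — same expectation as simulating noisy outcomes on
a 10000-subject validation set, but with less Monte-Carlo variance.
Validation draws default to $10^4$.

The benchmark's nuisance specifications (`model_spec()`) cross a correct
or incorrect propensity model with a correct or incorrect outcome model
(CC/CI/IC/II). The incorrect outcome design $\{X, A, XA\}$ omits the
squares but *still spans the true treatment contrast* $A(x_1 + x_2 -
0.1)$; the incorrect propensity in scenario 2 is a harmless constant. A
green double-robustness test therefore establishes that single
misspecification is benign in these worlds — it does not establish
robustness to misspecifications that distort the treatment-interaction
structure itself, and real data can of course produce those. Scenario 3's
"correct"/"incorrect" propensity labels both denote fitted models that
converge to the constant truth, so that scenario stresses extreme weights,
not propensity bias; with roughly 12 treated subjects at $n = 500$ the
incorrect outcome design is rank-deficient in a noticeable fraction of
replicates, and those fits error by design rather than silently dropping
columns.

What the generator does **not** emulate: confounding by unmeasured
variables, non-Gaussian or heavy-tailed covariates, treatment effects
that violate the linear-rule class, censoring, or missing data.

## Comparators and inference

`qlearn()` implements regression-based Q-learning, by default with the
full two-way interaction design ($1 + p + \binom{p}{2} + 1 + p +
\binom{p}{2}$ columns; 112 at $p = 10$); `direct_aipwe_search()`
maximizes the raw (discontinuous) AIPW value over unit-norm linear rules
with a generic budget-limited random-restart pattern search — a
documented stand-in for the genetic-algorithm search sometimes used with
this estimator. `permutation_test()` assesses a covariate's contribution
to the rule: the statistic is $|\beta_j|$ from the full refitted pipeline
and the null permutes column $j$ of $X$, refitting nuisances and rule at
the original penalty. The statistic and permutation scheme are this
package's documented choices (only the test's existence and permutation
count are canonical); when covariate $j$ is independent of the remaining
data the test is exact by exchangeability.

## Worked example

```{r example, eval = FALSE}
sp <- scenario_spec(2)
train <- simulate_scenario(sp, 2000, seed = 1)
fit <- earl(train, nuisance = model_spec(2, "CC"),
            loss = "logistic", seed = 2)
coef(fit)
true_value(sp, fit, n_mc = 1e5, seed = 3)   # compare to optimal_value(sp)
```

## Known limitations

Linear rules only (no kernelized rule classes); no variance estimates for
value estimators or rule coefficients (inference is via the permutation
test); single-stage decisions only; nuisance models are parametric by
construction, though any object implementing `predict(object, X, a)` (or
a plain function) can be plugged in.
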