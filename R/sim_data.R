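#' Benchmark simulation scenarios
#'
#' Defines one of three generative models used throughout the package's
#' simulation benchmark. Covariates are iid standard normal,
#' `X = (X1, ..., Xp)`; treatment is assigned by a logistic model
#' `P(A = 1 | X) = plogis(l(X))`; and the outcome is
#' `Y = sum_j Xj^2 + sum_j Xj + A * c(X) + eps`, `eps ~ N(0, noise_sd^2)`,
#' with treatment-covariate contrast `c(x) = x1 + x2 - 0.1`.
#'
#' The scenarios differ only in treatment assignment:
#' * Scenario 1: `l(x) = x1 + x2 + x1*x2` (propensities reach extremes),
#' * Scenario 2: `l(x) = 0.5*x1 - 0.5` (propensities bounded away from 0/1),
#' * Scenario 3: as scenario 2 but `P(A = 1 | X) = 0.025` for everyone
#'   (a severely imbalanced design stressing inverse weighting).
#'
#' Because the truth is known, the spec exposes oracles: the true propensity,
#' the true Q-function, the optimal rule `d*(x) = sgn(c(x))` and its value.
#'
#' @param scenario Integer 1, 2 or 3.
#' @param p Covariate dimension (default 10; at least 2, since the contrast
#'   uses x1 and x2).
#' @param noise_sd Outcome noise standard deviation (default 1).
#' @return An object of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec(2)
#' d <- simulate_scenario(sp, n = 100, seed = 1)
#' @export
scenario_spec <- function(scenario, p = 10, noise_sd = 1) {
  scenario <- as.integer(scenario)
  if (length(scenario) != 1L || is.na(scenario) || !scenario %in% 1:3)
    stop("scenario_spec: scenario must be 1, 2 or 3")
  if (p < 2) stop("scenario_spec: p must be >= 2 (contrast uses x1, x2)")
  if (noise_sd <= 0) stop("scenario_spec: noise_sd must be positive")
  link <- if (scenario == 1) {
    function(X) X[, 1] + X[, 2] + X[, 1] * X[, 2]
  } else {
    function(X) 0.5 * X[, 1] - 0.5
  }
  structure(list(
    scenario = scenario,
    p = as.integer(p),
    link = link,
    contrast = function(X) X[, 1] + X[, 2] - 0.1,
    noise_sd = noise_sd,
    fixed_propensity = if (scenario == 3) 0.025 else NULL
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: scenario %d, p = %d, noise_sd = %g\n",
              x$scenario, x$p, x$noise_sd))
  if (!is.null(x$fixed_propensity))
    cat(sprintf("  fixed propensity P(A=1|X) = %g\n", x$fixed_propensity))
  invisible(x)
}

.as_X <- function(spec, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != spec$p)
    stop(sprintf("expected %d covariates, got %d", spec$p, ncol(X)))
  X
}

#' True treatment-assignment probability
#'
#' @param spec A [scenario_spec].
#' @param x Covariate vector (length p) or matrix (n x p).
#' @param a Treatment arm, -1 or +1 (scalar).
#' @return `P(A = a | X = x)` for each row of `x`.
#' @export
true_propensity <- function(spec, x, a) {
  if (length(a) != 1L || !a %in% c(-1, 1))
    stop("true_propensity: a must be -1 or +1")
  X <- .as_X(spec, x)
  p1 <- if (!is.null(spec$fixed_propensity)) {
    rep(spec$fixed_propensity, nrow(X))
  } else {
    stats::plogis(spec$link(X))
  }
  if (a == 1) p1 else 1 - p1
}

#' True outcome regression Q(x, a) = E(Y | X = x, A = a)
#'
#' @inheritParams true_propensity
#' @param a Treatment, scalar in \{-1, +1\} or a length-n vector.
#' @return Numeric vector of conditional mean outcomes.
#' @export
true_q <- function(spec, x, a) {
  X <- .as_X(spec, x)
  if (!all(a %in% c(-1, 1))) stop("true_q: a must be in {-1, +1}")
  rowSums(X^2) + rowSums(X) + a * spec$contrast(X)
}

#' Optimal treatment rule d*(x) = sgn(c(x)), with sgn(0) = +1
#'
#' @inheritParams true_propensity
#' @return Vector of optimal recommendations in \{-1, +1\}.
#' @export
optimal_rule <- function(spec, x) {
  sgn(spec$contrast(.as_X(spec, x)))
}

#' Simulate a dataset from a benchmark scenario
#'
#' @param spec A [scenario_spec].
#' @param n Sample size (>= 1).
#' @param seed Optional integer seed; runs with the same seed are
#'   bit-identical.
#' @return An [itr_data] object.
#' @export
simulate_scenario <- function(spec, n, seed = NULL) {
  if (n < 1) stop("simulate_scenario: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n * spec$p), n, spec$p)
  p1 <- true_propensity(spec, X, 1)
  A <- ifelse(stats::runif(n) < p1, 1, -1)
  Y <- rowSums(X^2) + rowSums(X) + A * spec$contrast(X) +
    stats::rnorm(n, sd = spec$noise_sd)
  itr_data(X, A, Y)
}

#' Monte-Carlo value of a treatment rule under the true generative model
#'
#' Computes `V(d) = E[Q(X, d(X))]` by averaging the true Q-function over
#' fresh covariate draws. No outcome noise enters: the value identity
#' `V(d) = E[Q(X, d(X))]` makes outcome draws unnecessary and halves the
#' Monte-Carlo variance relative to averaging noisy outcomes.
#'
#' @param spec A [scenario_spec].
#' @param rule A decision rule: a function mapping an n x p matrix to
#'   recommendations in \{-1, +1\}, or a fitted rule object with a
#'   `predict(, type = "class")` method.
#' @param n_mc Number of Monte-Carlo covariate draws (default 10000).
#' @param seed Optional seed for the validation draws.
#' @return Scalar Monte-Carlo estimate of the value.
#' @seealso [optimal_value()] for the closed-form optimum.
#' @export
true_value <- function(spec, rule, n_mc = 10000, seed = NULL) {
  if (n_mc < 1) stop("true_value: n_mc must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n_mc * spec$p), n_mc, spec$p)
  d <- .apply_rule(rule, X)
  mean(true_q(spec, X, d))
}

#' Closed-form value of the optimal rule
#'
#' Under the shared outcome model, `V* = p + E|c(X)|` where
#' `c(X) = X1 + X2 - 0.1 ~ N(-0.1, 2)`; the folded-normal mean gives
#' `E|c(X)| = sigma*sqrt(2/pi)*exp(-mu^2/(2*sigma^2)) + mu*(2*Phi(mu/sigma) - 1)`
#' with `mu = -0.1`, `sigma = sqrt(2)`. For p = 10 this is about 11.131.
#'
#' @param spec A [scenario_spec].
#' @return Scalar V*.
#' @export
optimal_value <- function(spec) {
  mu <- -0.1
  s <- sqrt(2)
  e_abs_c <- s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
    mu * (2 * stats::pnorm(mu / s) - 1)
  spec$p + e_abs_c
}
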