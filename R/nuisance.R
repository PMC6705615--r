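#' Benchmark nuisance-model specifications (CC / CI / IC / II)
#'
#' Returns the propensity and outcome-regression term lists used in the
#' simulation benchmark. The first letter says whether the propensity model
#' is Correct or Incorrect, the second letter the same for the outcome
#' model:
#'
#' * correct propensity: logistic with predictors \{x1, x2, x1*x2\} in
#'   scenario 1, \{x1\} in scenarios 2 and 3;
#' * incorrect propensity: logistic on all main effects in scenario 1,
#'   intercept-only in scenarios 2 and 3;
#' * correct outcome: linear in \{X, X^2, A, x1*A, x2*A\};
#' * incorrect outcome: linear in \{X, A, X*A\} (no squares).
#'
#' Scenario 3 shares scenario 2's term lists; its generative propensity is a
#' constant 0.025, so the "correct" label there refers to the scenario-2
#' functional form.
#'
#' @param scenario Integer 1, 2 or 3.
#' @param which One of "CC", "CI", "IC", "II".
#' @return An object of class `nuisance_spec` with elements `scenario`,
#'   `which`, `propensity` and `outcome` (design kinds).
#' @export
model_spec <- function(scenario, which = c("CC", "CI", "IC", "II")) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop("model_spec: scenario must be 1, 2 or 3")
  which <- match.arg(which)
  prop_ok <- substr(which, 1, 1) == "C"
  out_ok <- substr(which, 2, 2) == "C"
  propensity <- if (scenario == 1) {
    if (prop_ok) "x1+x2+x1x2" else "main"
  } else {
    if (prop_ok) "x1" else "intercept"
  }
  structure(list(
    scenario = scenario,
    which = which,
    propensity = propensity,
    outcome = if (out_ok) "quadratic" else "linear"
  ), class = "nuisance_spec")
}

#' @export
print.nuisance_spec <- function(x, ...) {
  cat(sprintf("nuisance_spec: scenario %d, %s (propensity: %s, outcome: %s)\n",
              x$scenario, x$which, x$propensity, x$outcome))
  invisible(x)
}

# Design matrix (no intercept column) for a propensity kind.
propensity_design <- function(kind, X) {
  switch(kind,
    "x1+x2+x1x2" = cbind(x1 = X[, 1], x2 = X[, 2], `x1:x2` = X[, 1] * X[, 2]),
    "x1" = cbind(x1 = X[, 1]),
    "main" = X,
    "intercept" = matrix(numeric(0), nrow(X), 0),
    stop(sprintf("unknown propensity design kind '%s'", kind))
  )
}

# Design matrix (no intercept column) for an outcome kind, at treatment a
# (scalar or length-n vector).
outcome_design <- function(kind, X, a) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  a <- rep_len(a, nrow(X))
  sq <- X^2
  colnames(sq) <- paste0(colnames(X), "^2")
  switch(kind,
    quadratic = cbind(X, sq, a = a, `x1:a` = X[, 1] * a, `x2:a` = X[, 2] * a),
    linear = {
      XA <- X * a
      colnames(XA) <- paste0(colnames(X), ":a")
      cbind(X, a = a, XA)
    },
    stop(sprintf("unknown outcome design kind '%s'", kind))
  )
}

.prop_kind <- function(spec) {
  if (inherits(spec, "nuisance_spec")) spec$propensity else as.character(spec)
}
.out_kind <- function(spec) {
  if (inherits(spec, "nuisance_spec")) spec$outcome else as.character(spec)
}

#' Fit a logistic propensity model
#'
#' Maximum-likelihood (or, with `ridge > 0`, ridge-penalized) logistic
#' regression of `I(A = +1)` on the specification's terms. Predicted
#' probabilities are clipped into `clip` to enforce positivity: extreme
#' estimated propensities yield unbounded inverse weights, so downstream
#' weights are guaranteed finite. The default bounds (0.01, 0.99) keep the
#' scenario-3 truth of 0.025 representable.
#'
#' @param data An [itr_data] object.
#' @param spec A [model_spec] object (or a propensity design kind string).
#' @param ridge Ridge penalty (glmnet lambda, alpha = 0, standardized
#'   features, intercept unpenalized). 0 = plain ML.
#' @param clip Length-2 probability clipping bounds, 0 < lo <= hi < 1.
#' @return A `propensity_model`; use `predict(model, X, a)` for clipped
#'   probabilities `P(A = a | X = x)`.
#' @export
fit_propensity <- function(data, spec, ridge = 0, clip = c(0.01, 0.99)) {
  stopifnot(length(clip) == 2, clip[1] > 0, clip[2] < 1, clip[1] <= clip[2])
  kind <- .prop_kind(spec)
  D <- propensity_design(kind, data$X)
  y01 <- (data$A + 1) / 2
  if (ridge > 0 && ncol(D) >= 2) {
    fit <- glmnet::glmnet(D, y01, family = "binomial", alpha = 0,
                          lambda = ridge, standardize = TRUE)
    coefs <- as.numeric(stats::coef(fit, s = ridge))
  } else {
    M <- cbind(`(Intercept)` = 1, D)
    fit <- suppressWarnings(
      stats::glm.fit(M, y01, family = stats::binomial())
    )
    coefs <- fit$coefficients
    if (anyNA(coefs))
      stop(sprintf("fit_propensity: collinear terms (%s)",
                   paste(colnames(M)[is.na(coefs)], collapse = ", ")))
    pf <- fit$fitted.values
    if (ridge == 0 && (any(pf > 1 - 1e-8) || any(pf < 1e-8)))
      stop(paste("fit_propensity: fitted probabilities numerically 0 or 1",
                 "(perfect or quasi-separation); refit with ridge > 0"))
  }
  structure(list(kind = kind, coefficients = coefs, clip = clip,
                 ridge = ridge), class = "propensity_model")
}

#' @export
predict.propensity_model <- function(object, X, a, ...) {
  D <- propensity_design(object$kind, X)
  eta <- drop(cbind(1, D) %*% object$coefficients)
  p1 <- stats::plogis(eta)
  p <- ifelse(rep_len(a, nrow(X)) == 1, p1, 1 - p1)
  pmin(pmax(p, object$clip[1]), object$clip[2])
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity_model (logistic, design '%s', ridge = %g)\n",
              x$kind, x$ridge))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit a linear outcome-regression model
#'
#' Ordinary least squares of Y on the specification's terms.
#'
#' @inheritParams fit_propensity
#' @param spec A [model_spec] object (or an outcome design kind string).
#' @return An `outcome_model`; use `predict(model, X, a)` for fitted
#'   `Q(x, a)`.
#' @export
fit_outcome <- function(data, spec) {
  kind <- .out_kind(spec)
  M <- cbind(`(Intercept)` = 1, outcome_design(kind, data$X, data$A))
  qrm <- qr(M)
  if (qrm$rank < ncol(M)) {
    bad <- colnames(M)[qrm$pivot[(qrm$rank + 1):ncol(M)]]
    stop(sprintf("fit_outcome: rank-deficient design; collinear terms: %s",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qrm, data$Y)
  structure(list(kind = kind, coefficients = coefs), class = "outcome_model")
}

#' @export
predict.outcome_model <- function(object, X, a, ...) {
  if (identical(object$kind, "zero")) return(rep(0, nrow(X)))
  D <- outcome_design(object$kind, X, a)
  drop(cbind(1, D) %*% object$coefficients)
}

#' @export
print.outcome_model <- function(x, ...) {
  if (identical(x$kind, "zero")) {
    cat("outcome_model: identically zero (pure inverse weighting)\n")
  } else {
    cat(sprintf("outcome_model (OLS, design '%s')\n", x$kind))
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' The identically-zero outcome model
#'
#' Plugging this into the AIPW weights reduces them to pure inverse
#' probability weights, which is how outcome weighted learning arises as a
#' special case of the doubly robust estimator.
#'
#' @return An `outcome_model` predicting 0 for every (x, a).
#' @export
zero_outcome <- function() {
  structure(list(kind = "zero", coefficients = numeric(0)),
            class = "outcome_model")
}

# Dispatch helpers so downstream code accepts either fitted model objects or
# plain prediction functions(X, a) -- the pluggable nuisance contract.
.predict_prop <- function(prop, X, a) {
  p <- if (is.function(prop)) prop(X, a) else stats::predict(prop, X, a)
  p <- rep_len(as.numeric(p), nrow(X))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("propensity predictions must lie strictly inside (0, 1)")
  p
}

.predict_out <- function(out, X, a) {
  q <- if (is.function(out)) out(X, a) else stats::predict(out, X, a)
  rep_len(as.numeric(q), nrow(X))
}

#' Cross-fitted nuisance models
#'
#' Randomly partitions subjects into K folds of near-equal size and fits the
#' propensity and outcome models on each fold `I_k` alone. In the
#' sample-splitting estimator the models from fold k are applied to the
#' complement `I_(-k)`, so the nuisance estimates and the rule-fitting sample
#' are independent. (Note the orientation: the nuisances are fit on the
#' *small* fold, the rule on the complement.)
#'
#' @param data An [itr_data] object.
#' @param spec A [model_spec].
#' @param K Number of folds (small integer, default 2).
#' @param seed Optional seed for the fold assignment.
#' @param ridge,clip Passed to [fit_propensity()].
#' @return A `crossfit_plan`: list with `folds` (length-n fold index) and
#'   `models` (per-fold list of `propensity` and `outcome` fits).
#' @export
crossfit_nuisance <- function(data, spec, K = 2, seed = NULL, ridge = 0,
                              clip = c(0.01, 0.99)) {
  n <- nrow(data$X)
  if (K < 2) stop("crossfit_nuisance: K must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(K), n))
  models <- lapply(seq_len(K), function(k) {
    dk <- data[folds == k]
    if (nrow(dk$X) <= ncol(dk$X) + 2)
      stop(sprintf("crossfit_nuisance: fold %d too small to fit models", k))
    list(propensity = fit_propensity(dk, spec, ridge = ridge, clip = clip),
         outcome = fit_outcome(dk, spec))
  })
  structure(list(folds = folds, models = models, K = K, spec = spec),
            class = "crossfit_plan")
}

#' @export
print.crossfit_plan <- function(x, ...) {
  cat(sprintf("crossfit_plan: K = %d folds, sizes %s\n", x$K,
              paste(tabulate(x$folds, x$K), collapse = "/")))
  invisible(x)
}
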