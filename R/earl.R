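#' Linear decision rule
#'
#' A rule `d(x) = sgn{f(x)}` with `f(x) = b0 + x' beta` and the convention
#' `sgn(0) = +1`. The ridge penalty in the fitting objective applies to
#' `beta` only (standard offset convention; the intercept is unpenalized).
#'
#' @param intercept Scalar b0.
#' @param coefficients Length-p numeric beta.
#' @return An object of class `linear_rule`.
#' @export
linear_rule <- function(intercept, coefficients) {
  stopifnot(length(intercept) == 1, is.finite(intercept),
            all(is.finite(coefficients)))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = as.numeric(coefficients)),
            class = "linear_rule")
}

#' @export
predict.linear_rule <- function(object, X, type = c("class", "link"), ...) {
  type <- match.arg(type)
  f <- object$intercept + drop(as.matrix(X) %*% object$coefficients)
  if (type == "link") f else sgn(f)
}

#' @export
print.linear_rule <- function(x, ...) {
  cat("linear_rule: f(x) = b0 + x'beta, d(x) = sgn{f(x)}\n")
  print(round(c(`(Intercept)` = x$intercept,
                stats::setNames(x$coefficients,
                                paste0("x", seq_along(x$coefficients)))), 4))
  invisible(x)
}

#' @export
coef.linear_rule <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$coefficients,
                    paste0("x", seq_along(object$coefficients))))
}

#' Penalized empirical surrogate risk
#'
#' The objective minimized by the doubly robust rule estimator:
#' `mean( |W_1| phi{sgn(W_1) f(X)} + |W_-1| phi{-sgn(W_-1) f(X)} )
#'  + lambda * ||beta||^2`,
#' with sgn(0) = +1 (zero weights contribute 0 either way).
#'
#' @param rule A [linear_rule].
#' @param X Covariate matrix.
#' @param weights A `weight_set`.
#' @param loss A [surrogate_loss] or its name.
#' @param lambda Non-negative ridge penalty on the slope coefficients.
#' @return Scalar objective value.
#' @export
earl_objective <- function(rule, X, weights, loss, lambda) {
  stopifnot(lambda >= 0)
  loss <- .as_loss(loss)
  f <- predict(rule, X, type = "link")
  s1 <- sgn(weights$w_plus)
  sm <- sgn(weights$w_minus)
  mean(abs(weights$w_plus) * loss$phi(s1 * f) +
         abs(weights$w_minus) * loss$phi(-sm * f)) +
    lambda * sum(rule$coefficients^2)
}

# Fast path: objective/gradient on precomputed pieces. par = c(b0, beta).
.earl_fn <- function(par, X, aw1, awm, s1, sm, phi, lambda) {
  f <- par[1] + drop(X %*% par[-1])
  mean(aw1 * phi(s1 * f) + awm * phi(-sm * f)) + lambda * sum(par[-1]^2)
}

.earl_gr <- function(par, X, aw1, awm, s1, sm, grad, lambda) {
  f <- par[1] + drop(X %*% par[-1])
  g <- aw1 * s1 * grad(s1 * f) - awm * sm * grad(-sm * f)
  n <- length(f)
  c(mean(g), drop(crossprod(X, g)) / n + 2 * lambda * par[-1])
}

#' Minimize the penalized surrogate risk over linear rules
#'
#' Deterministic convex optimization initialized at the zero rule. Smooth
#' losses (logistic, exponential, squared hinge) use BFGS with analytic
#' gradients; the hinge loss uses a smoothing continuation (Huber-smoothed
#' hinge with smoothing parameter decreasing to 1e-4, warm-started), whose
#' solutions are certified against a grid-search oracle in the test suite.
#'
#' @param X Covariate matrix (n x p).
#' @param weights A `weight_set`.
#' @param loss A [surrogate_loss] or its name.
#' @param lambda Positive ridge penalty (coercivity in beta).
#' @param control List: `maxit` (default 2000), `reltol` (1e-12),
#'   `hinge_deltas` (smoothing schedule, default 0.5, 0.05, 0.005, 1e-4).
#' @return List with `rule` ([linear_rule]), `objective`, `iterations`,
#'   `converged`, `grad_norm` (smooth losses; NA for hinge).
#' @export
minimize_earl <- function(X, weights, loss, lambda, control = list()) {
  stopifnot(lambda > 0, nrow(X) >= 1)
  loss <- .as_loss(loss)
  ctrl <- utils::modifyList(
    list(maxit = 2000, reltol = 1e-12,
         hinge_deltas = c(0.5, 0.05, 0.005, 1e-4)), control)
  X <- as.matrix(X)
  aw1 <- abs(weights$w_plus)
  awm <- abs(weights$w_minus)
  s1 <- sgn(weights$w_plus)
  sm <- sgn(weights$w_minus)
  par <- numeric(ncol(X) + 1)
  iters <- 0L

  run_bfgs <- function(par, phi, grad) {
    stats::optim(
      par,
      function(p) .earl_fn(p, X, aw1, awm, s1, sm, phi, lambda),
      function(p) .earl_gr(p, X, aw1, awm, s1, sm, grad, lambda),
      method = "BFGS",
      control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  }

  if (loss$name == "hinge") {
    for (delta in ctrl$hinge_deltas) {
      sh <- .smoothed_hinge(delta)
      res <- run_bfgs(par, sh$phi, sh$grad)
      par <- res$par
      iters <- iters + res$counts[1]
    }
    grad_norm <- NA_real_
  } else {
    res <- run_bfgs(par, loss$phi, loss$grad)
    par <- res$par
    iters <- iters + res$counts[1]
    grad_norm <- sqrt(sum(.earl_gr(par, X, aw1, awm, s1, sm,
                                   loss$grad, lambda)^2))
  }
  if (res$convergence != 0)
    stop(sprintf(paste("minimize_earl: optimizer did not converge",
                       "(code %d, %d iterations, objective %.6g)"),
                 res$convergence, iters, res$value))
  obj <- .earl_fn(par, X, aw1, awm, s1, sm, loss$phi, lambda)
  list(rule = linear_rule(par[1], par[-1]), objective = obj,
       iterations = as.integer(iters), converged = TRUE,
       grad_norm = grad_norm)
}

#' Select the ridge penalty by cross-validating the value
#'
#' For each candidate lambda, runs V-fold cross-validation: the rule is fit
#' on the training folds and the normalized IPW value of its
#' recommendations is computed on the held-out fold. Returns the lambda
#' maximizing the mean held-out value; exact ties break toward the larger
#' lambda (the more penalized, simpler rule). Folds with no rule-concordant
#' subject contribute NA and are dropped from the mean; if every fold is
#' undefined for every lambda, an error is raised.
#'
#' @param data An [itr_data] object (the sample the rule is being fit on).
#' @param weights A `weight_set` computed on `data`.
#' @param propensity Propensity model used for the held-out value (the same
#'   one that produced `weights`).
#' @param loss A [surrogate_loss] or its name.
#' @param lambda_grid Positive candidate penalties (default `2^(-5:5)`).
#' @param cv_folds Number of folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @param control Passed to [minimize_earl()].
#' @return List with `lambda` (chosen) and `cv_table`
#'   (data.frame of lambda and mean held-out value).
#' @export
cv_select_lambda <- function(data, weights, propensity, loss,
                             lambda_grid = 2^(-5:5), cv_folds = 10,
                             seed = NULL, control = list()) {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid > 0), cv_folds >= 2)
  loss <- .as_loss(loss)
  n <- nrow(data$X)
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  pA <- .predict_prop(propensity, data$X, data$A)
  cv_value <- vapply(lambda_grid, function(lam) {
    vals <- vapply(seq_len(cv_folds), function(v) {
      tr <- folds != v
      fit <- minimize_earl(data$X[tr, , drop = FALSE], weights[tr],
                           loss, lam, control)
      ho <- which(!tr)
      d <- predict(fit$rule, data$X[ho, , drop = FALSE], type = "class")
      Id <- as.numeric(data$A[ho] == d)
      den <- sum(Id / pA[ho])
      if (den <= 0) NA_real_ else sum(data$Y[ho] * Id / pA[ho]) / den
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(cv_value)))
    stop("cv_select_lambda: held-out value undefined for every lambda")
  best <- max(cv_value, na.rm = TRUE)
  lambda <- max(lambda_grid[!is.na(cv_value) & cv_value == best])
  list(lambda = lambda,
       cv_table = data.frame(lambda = lambda_grid, value = cv_value))
}

#' Doubly robust rule estimation with a convex surrogate loss
#'
#' Fits a linear individualized treatment rule by minimizing the penalized
#' surrogate relaxation of the (negated) AIPW value estimator. Nuisance
#' models may be supplied prefit, as plain prediction functions, or fit
#' internally from a [model_spec]. The resulting rule is doubly robust:
#' consistent for the optimal rule whenever either nuisance model is
#' correctly specified.
#'
#' @param data An [itr_data] object.
#' @param propensity Prefit `propensity_model`, or function `(X, a)`.
#'   Ignored if `nuisance` is given.
#' @param outcome Prefit `outcome_model` or function `(X, a)`; `NULL` means
#'   [zero_outcome()] (pure inverse weighting). Ignored if `nuisance` given.
#' @param nuisance Optional [model_spec]; when supplied, both nuisance
#'   models are fit on `data` (same-sample plug-in fit; see [earl_split()]
#'   for the sample-splitting variant).
#' @param loss Surrogate loss name or [surrogate_loss]
#'   (default `"logistic"`).
#' @param lambda Ridge penalty; `NULL` (default) selects it by
#'   cross-validated value over `lambda_grid`.
#' @param lambda_grid,cv_folds,seed Passed to [cv_select_lambda()].
#' @param ridge,clip Passed to [fit_propensity()] when `nuisance` is given.
#' @param control Optimizer control, see [minimize_earl()].
#' @return Object of class `earl`: list with `rule` ([linear_rule]),
#'   `lambda`, `cv_table` (if CV ran), `objective`, `loss`, `diagnostics`,
#'   and the nuisance models and weights used.
#' @examples
#' sp <- scenario_spec(2)
#' d <- simulate_scenario(sp, 400, seed = 1)
#' fit <- earl(d, nuisance = model_spec(2, "CC"), lambda = 0.25)
#' coef(fit$rule)
#' @export
earl <- function(data, propensity = NULL, outcome = NULL, nuisance = NULL,
                 loss = "logistic", lambda = NULL, lambda_grid = 2^(-5:5),
                 cv_folds = 10, ridge = 0, clip = c(0.01, 0.99),
                 seed = NULL, control = list()) {
  loss <- .as_loss(loss)
  if (!is.null(nuisance)) {
    propensity <- fit_propensity(data, nuisance, ridge = ridge, clip = clip)
    outcome <- fit_outcome(data, nuisance)
  }
  if (is.null(propensity))
    stop("earl: supply either a propensity model or a nuisance spec")
  if (is.null(outcome)) outcome <- zero_outcome()
  w <- aipw_weights(data, propensity, outcome)
  cv_table <- NULL
  if (is.null(lambda)) {
    sel <- cv_select_lambda(data, w, propensity, loss, lambda_grid,
                            cv_folds, seed = seed, control = control)
    lambda <- sel$lambda
    cv_table <- sel$cv_table
  }
  fit <- minimize_earl(data$X, w, loss, lambda, control)
  structure(list(
    rule = fit$rule, lambda = lambda, cv_table = cv_table,
    objective = fit$objective, loss = loss$name,
    diagnostics = list(iterations = fit$iterations,
                       converged = fit$converged,
                       grad_norm = fit$grad_norm),
    propensity = propensity, outcome = outcome, weights = w
  ), class = "earl")
}

#' @export
predict.earl <- function(object, X, type = c("class", "link"), ...) {
  predict(object$rule, X, type = match.arg(type))
}

#' @export
print.earl <- function(x, ...) {
  cat(sprintf("earl fit: %s loss, lambda = %g, objective = %.4f\n",
              x$loss, x$lambda, x$objective))
  print(x$rule)
  invisible(x)
}

#' @export
coef.earl <- function(object, ...) coef(object$rule)

#' Outcome weighted learning
#'
#' The special case of the doubly robust estimator with hinge loss and an
#' identically-zero outcome model: weighted classification with weights
#' `Y/pi(A; X)` on rule-concordant subjects. Delegates to the [earl()] path,
#' so the two calls are bit-identical.
#'
#' @inheritParams earl
#' @param propensity Propensity model (typically the known randomization
#'   probability, or a fitted model on observational data).
#' @return An object of class `earl` (with `loss = "hinge"`).
#' @export
owl <- function(data, propensity, lambda = NULL, lambda_grid = 2^(-5:5),
                cv_folds = 10, seed = NULL, control = list()) {
  earl(data, propensity = propensity, outcome = zero_outcome(),
       loss = "hinge", lambda = lambda, lambda_grid = lambda_grid,
       cv_folds = cv_folds, seed = seed, control = control)
}

#' Sample-splitting estimator with rule aggregation
#'
#' K-fold variant removing the dependence between nuisance estimation and
#' rule fitting: for each fold k the nuisance models are fit on `I_k` alone
#' and the rule is fit on the complement `I_(-k)` (with its own
#' cross-validated penalty), then the K linear rules are aggregated by
#' averaging their coefficients — valid because the linear class is closed
#' under averaging. The reported `value_bar` is the mean over folds of the
#' AIPW value of each fold's rule evaluated on `I_(-k)` with that fold's
#' nuisance models.
#'
#' @inheritParams earl
#' @param nuisance A [model_spec] (required: per-fold nuisance fits).
#' @param K Number of folds (small integer, default 2).
#' @return Object of class `earl_split`: `rule` (aggregated
#'   [linear_rule]), `per_fold` (list with each fold's rule and lambda),
#'   `value_bar`, `folds`, `loss`.
#' @export
earl_split <- function(data, nuisance, K = 2, loss = "logistic",
                       lambda = NULL, lambda_grid = 2^(-5:5), cv_folds = 10,
                       ridge = 0, clip = c(0.01, 0.99), seed = NULL,
                       control = list()) {
  loss <- .as_loss(loss)
  if (!inherits(nuisance, "nuisance_spec"))
    stop("earl_split: 'nuisance' must be a model_spec()")
  plan <- crossfit_nuisance(data, nuisance, K = K, seed = seed,
                            ridge = ridge, clip = clip)
  per_fold <- vector("list", K)
  fold_values <- numeric(K)
  for (k in seq_len(K)) {
    rest <- plan$folds != k
    d_rest <- data[rest]
    mk <- plan$models[[k]]
    w <- aipw_weights(d_rest, mk$propensity, mk$outcome)
    lam <- lambda
    if (is.null(lam)) {
      sel <- cv_select_lambda(d_rest, w, mk$propensity, loss, lambda_grid,
                              cv_folds,
                              seed = if (is.null(seed)) NULL else seed + k,
                              control = control)
      lam <- sel$lambda
    }
    fit <- minimize_earl(d_rest$X, w, loss, lam, control)
    per_fold[[k]] <- list(rule = fit$rule, lambda = lam,
                          objective = fit$objective)
    fold_values[k] <- aipwe_value(d_rest, fit$rule, mk$propensity,
                                  mk$outcome)
  }
  b0 <- mean(vapply(per_fold, function(f) f$rule$intercept, numeric(1)))
  B <- rowMeans(matrix(
    vapply(per_fold, function(f) f$rule$coefficients,
           numeric(ncol(data$X))),
    nrow = ncol(data$X)))
  structure(list(rule = linear_rule(b0, B), per_fold = per_fold,
                 value_bar = mean(fold_values), folds = plan$folds,
                 loss = loss$name, K = K),
            class = "earl_split")
}

#' @export
predict.earl_split <- function(object, X, type = c("class", "link"), ...) {
  predict(object$rule, X, type = match.arg(type))
}

#' @export
print.earl_split <- function(x, ...) {
  cat(sprintf("earl_split: K = %d folds, %s loss, aggregated value %.4f\n",
              x$K, x$loss, x$value_bar))
  print(x$rule)
  invisible(x)
}

#' @export
coef.earl_split <- function(object, ...) coef(object$rule)
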