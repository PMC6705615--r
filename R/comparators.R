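#' Q-learning comparator
#'
#' Indirect (regression-based) rule estimation: fit a linear model for
#' Q(x, a) by OLS and recommend `d(x) = sgn{Q(x, +1) - Q(x, -1)}` with
#' sgn(0) = +1. By default the design contains an intercept, all main
#' effects, all pairwise covariate products, the treatment, and the
#' treatment interacted with every main effect and pairwise product —
#' `1 + p + choose(p, 2) + 1 + (p + choose(p, 2))` columns (112 at p = 10).
#' Supplying `spec` instead fits the benchmark's correct/incorrect outcome
#' term lists (the ".C"/".I" arms).
#'
#' @param data An [itr_data] object.
#' @param spec Optional [model_spec]; if given, its outcome design is used
#'   instead of the two-way interaction design.
#' @return Object of class `qlearn` with a
#'   `predict(, X, type = c("class", "contrast"))` method.
#' @export
qlearn <- function(data, spec = NULL) {
  if (is.null(spec)) {
    M <- .ql_expand(data$X)
    D <- cbind(`(Intercept)` = 1, M, a = data$A, M * data$A)
    colnames(D)[(ncol(M) + 3):ncol(D)] <- paste0(colnames(M), ":a")
    kind <- "interaction"
  } else {
    kind <- .out_kind(spec)
    D <- cbind(`(Intercept)` = 1, outcome_design(kind, data$X, data$A))
  }
  if (nrow(D) <= ncol(D))
    stop("qlearn: sample size must exceed the design dimension")
  qrm <- qr(D)
  if (qrm$rank < ncol(D))
    stop(sprintf("qlearn: rank-deficient design; collinear terms: %s",
                 paste(colnames(D)[qrm$pivot[(qrm$rank + 1):ncol(D)]],
                       collapse = ", ")))
  structure(list(kind = kind, coefficients = qr.coef(qrm, data$Y),
                 p = ncol(data$X)),
            class = "qlearn")
}

# Main effects plus all pairwise products x_i * x_j, i < j.
.ql_expand <- function(X) {
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (p < 2) return(X)
  pairs <- utils::combn(p, 2)
  P <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  colnames(P) <- paste0(colnames(X)[pairs[1, ]], ":", colnames(X)[pairs[2, ]])
  cbind(X, P)
}

#' Full Q-learning design matrix
#'
#' Exposed for inspection; `qlearn()` fits OLS on exactly this matrix.
#'
#' @param X Covariate matrix.
#' @param A Treatment vector in \{-1, +1\}.
#' @return Numeric design matrix including the intercept column.
#' @export
qlearn_design <- function(X, A) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- .ql_expand(X)
  D <- cbind(`(Intercept)` = 1, M, a = A, M * A)
  colnames(D)[(ncol(M) + 3):ncol(D)] <- paste0(colnames(M), ":a")
  D
}

#' @export
predict.qlearn <- function(object, X, type = c("class", "contrast"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  q1 <- .ql_q(object, X, 1)
  qm1 <- .ql_q(object, X, -1)
  contrast <- q1 - qm1
  if (type == "contrast") contrast else sgn(contrast)
}

.ql_q <- function(object, X, a) {
  if (object$kind == "interaction") {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    M <- .ql_expand(X)
    D <- cbind(1, M, rep(a, nrow(X)), M * a)
  } else {
    D <- cbind(1, outcome_design(object$kind, X, a))
  }
  drop(D %*% object$coefficients)
}

#' @export
print.qlearn <- function(x, ...) {
  cat(sprintf("qlearn fit ('%s' design, %d coefficients)\n",
              x$kind, length(x$coefficients)))
  invisible(x)
}

#' Direct search of the AIPW value over linear rules
#'
#' Comparator that maximizes the AIPW value estimator directly over linear
#' rules normalized to the unit sphere, using a generic derivative-free
#' global search (random restarts followed by a coordinate pattern search
#' with shrinking steps), limited to `budget` value evaluations. The
#' discontinuous objective makes this slower and noisier than the convex
#' surrogate path; it is provided for benchmarking.
#'
#' @param data An [itr_data] object.
#' @param propensity,outcome Nuisance models (see [aipw_weights()]).
#' @param budget Total number of AIPW value evaluations (default 2000).
#' @param seed Optional seed (random restarts).
#' @return A [linear_rule] with attributes `value` (achieved AIPW value)
#'   and `evaluations`.
#' @export
direct_aipwe_search <- function(data, propensity, outcome, budget = 2000,
                                seed = NULL) {
  stopifnot(budget >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- aipw_weights(data, propensity, outcome)
  X1 <- cbind(1, data$X)  # value of d = sgn(X1 %*% par)
  value_of <- function(par) {
    d <- sgn(drop(X1 %*% par))
    mean(ifelse(d == 1, w$w_plus, w$w_minus))
  }
  k <- ncol(X1)
  # deterministic anchors: the two constant rules
  cand <- rbind(c(1, numeric(k - 1)), c(-1, numeric(k - 1)))
  n_random <- max(0, min(budget - nrow(cand), ceiling(budget * 0.6)))
  if (n_random > 0) {
    R <- matrix(stats::rnorm(n_random * k), n_random, k)
    cand <- rbind(cand, R / sqrt(rowSums(R^2)))
  }
  vals <- apply(cand, 1, value_of)
  used <- nrow(cand)
  best <- cand[which.max(vals), ]
  best_v <- max(vals)
  step <- 0.5
  while (used < budget && step > 1e-4) {
    improved <- FALSE
    for (j in seq_len(k)) {
      for (s in c(step, -step)) {
        if (used >= budget) break
        prop <- best
        prop[j] <- prop[j] + s
        prop <- prop / sqrt(sum(prop^2))
        v <- value_of(prop)
        used <- used + 1
        if (v > best_v) {
          best <- prop
          best_v <- v
          improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  rule <- linear_rule(best[1], best[-1])
  attr(rule, "value") <- best_v
  attr(rule, "evaluations") <- used
  rule
}

#' Permutation test for a rule coefficient
#'
#' Tests whether covariate `j` contributes to the fitted treatment rule.
#' The observed statistic is `|beta_j|` from the full pipeline (nuisance
#' fits plus surrogate-loss rule fit at a fixed penalty). Null replicates
#' are generated by permuting column `j` of X across subjects and re-running
#' the entire pipeline, so the null statistic reflects all estimation steps.
#' The p-value uses the add-one formula
#' `p = (1 + #\{null >= observed\}) / (B + 1)`; when covariate `j` is
#' independent of the remaining data the test is exact.
#'
#' @param data An [itr_data] object.
#' @param nuisance A [model_spec] refit on each permuted dataset.
#' @param covariate Column index j of the covariate under test.
#' @param B Number of permutations (default 199).
#' @param loss Surrogate loss (default logistic).
#' @param lambda Fixed ridge penalty used for the observed and all null
#'   fits; `NULL` selects it once on the observed data by CV and then
#'   holds it fixed.
#' @param ridge,clip Passed to [fit_propensity()].
#' @param seed Optional seed (permutations, and CV if `lambda = NULL`).
#' @param lambda_grid,cv_folds CV settings when `lambda = NULL`.
#' @return List of class `earl_permtest`: `p.value`, `statistic`,
#'   `null_statistics`, `B`, `covariate`, `lambda`.
#' @export
permutation_test <- function(data, nuisance, covariate, B = 199,
                             loss = "logistic", lambda = 0.25,
                             ridge = 0, clip = c(0.01, 0.99), seed = NULL,
                             lambda_grid = 2^(-5:5), cv_folds = 10) {
  stopifnot(B >= 1, covariate >= 1, covariate <= ncol(data$X))
  loss <- .as_loss(loss)
  if (!is.null(seed)) set.seed(seed)
  fit_once <- function(d, lam) {
    prop <- fit_propensity(d, nuisance, ridge = ridge, clip = clip)
    out <- fit_outcome(d, nuisance)
    w <- aipw_weights(d, prop, out)
    if (is.null(lam)) {
      lam <- cv_select_lambda(d, w, prop, loss, lambda_grid,
                              cv_folds)$lambda
    }
    list(rule = minimize_earl(d$X, w, loss, lam)$rule, lambda = lam)
  }
  obs_fit <- fit_once(data, lambda)
  lambda <- obs_fit$lambda
  obs <- abs(obs_fit$rule$coefficients[covariate])
  null_stats <- vapply(seq_len(B), function(b) {
    d <- data
    d$X[, covariate] <- d$X[sample(nrow(d$X)), covariate]
    abs(fit_once(d, lambda)$rule$coefficients[covariate])
  }, numeric(1))
  structure(list(p.value = (1 + sum(null_stats >= obs)) / (B + 1),
                 statistic = obs, null_statistics = null_stats, B = B,
                 covariate = covariate, lambda = lambda),
            class = "earl_permtest")
}

#' @export
print.earl_permtest <- function(x, ...) {
  cat(sprintf(
    "permutation test: covariate x%d, |beta| = %.4f, B = %d, p = %.4f\n",
    x$covariate, x$statistic, x$B, x$p.value))
  invisible(x)
}
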