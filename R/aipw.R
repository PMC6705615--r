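#' AIPW misclassification weights
#'
#' For each subject and each arm `a` in \{-1, +1\}, computes the augmented
#' inverse probability weight
#' `W_a = Y * I(A = a) / pi(a; X) - {I(A = a) - pi(a; X)} / pi(a; X) * Q(X, a)`.
#' These are the per-subject building blocks of the doubly robust value
#' estimator: the value of any rule d is the sample mean of `W_{d(X_i)}`, and
#' rule estimation becomes weighted classification with labels
#' `sgn(W_a) * a` and weights `|W_a|`. With a zero outcome model the weights
#' reduce to pure inverse probability weights `Y I(A = a)/pi(a; X)`.
#'
#' @param data An [itr_data] object.
#' @param propensity A fitted `propensity_model`, or a function `(X, a)`
#'   returning probabilities in (0, 1).
#' @param outcome A fitted `outcome_model` (use [zero_outcome()] for pure
#'   inverse weighting), or a function `(X, a)`.
#' @return A `weight_set`: list with `w_plus` (arm +1), `w_minus` (arm -1)
#'   and logical `stabilized`.
#' @export
aipw_weights <- function(data, propensity, outcome) {
  X <- data$X
  p1 <- .predict_prop(propensity, X, 1)
  pm1 <- .predict_prop(propensity, X, -1)
  q1 <- .predict_out(outcome, X, 1)
  qm1 <- .predict_out(outcome, X, -1)
  i1 <- as.numeric(data$A == 1)
  im1 <- 1 - i1
  w_plus <- data$Y * i1 / p1 - (i1 - p1) / p1 * q1
  w_minus <- data$Y * im1 / pm1 - (im1 - pm1) / pm1 * qm1
  bad <- which(!is.finite(w_plus) | !is.finite(w_minus))
  if (length(bad))
    stop(sprintf("aipw_weights: non-finite weight for subject(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  structure(list(w_plus = w_plus, w_minus = w_minus, stabilized = FALSE),
            class = "weight_set")
}

#' Stabilized AIPW weights
#'
#' Divides each weight by the subject's inverse-propensity factor,
#' `SW_a = W_a / {I(A = a) / pi(a; X)}`, damping the variance inflation
#' caused by extreme propensities. For subjects whose observed treatment is
#' not `a` the literal formula divides by zero; those entries are set to 0
#' and the returned object carries `off_arm_zeroed = TRUE` to flag the
#' convention. On-arm, `SW_a = W_a * pi(a; X)`, and with a zero outcome
#' model `SW_a = Y`.
#'
#' @inheritParams aipw_weights
#' @return A `weight_set` with `stabilized = TRUE`.
#' @export
stabilized_weights <- function(data, propensity, outcome) {
  w <- aipw_weights(data, propensity, outcome)
  X <- data$X
  p1 <- .predict_prop(propensity, X, 1)
  pm1 <- .predict_prop(propensity, X, -1)
  on1 <- data$A == 1
  w$w_plus <- ifelse(on1, w$w_plus * p1, 0)
  w$w_minus <- ifelse(!on1, w$w_minus * pm1, 0)
  w$stabilized <- TRUE
  w$off_arm_zeroed <- TRUE
  w
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("weight_set (%s): n = %d\n",
              if (isTRUE(x$stabilized)) "stabilized" else "AIPW",
              length(x$w_plus)))
  cat(sprintf("  |W+1| mean %.3f max %.3f; |W-1| mean %.3f max %.3f\n",
              mean(abs(x$w_plus)), max(abs(x$w_plus)),
              mean(abs(x$w_minus)), max(abs(x$w_minus))))
  invisible(x)
}

#' @export
`[.weight_set` <- function(x, i, ...) {
  out <- x
  out$w_plus <- x$w_plus[i]
  out$w_minus <- x$w_minus[i]
  out
}

#' Inverse probability weighted value estimator
#'
#' `V_IPWE(d) = mean( Y * I{A = d(X)} / pi(A; X) )`: only subjects whose
#' observed treatment agrees with the rule contribute, reweighted by the
#' inverse propensity of the treatment they actually received.
#'
#' @inheritParams aipw_weights
#' @param rule A decision rule (function or fitted rule object).
#' @return Scalar value estimate.
#' @export
ipwe_value <- function(data, rule, propensity) {
  d <- .apply_rule(rule, data$X)
  pA <- .predict_prop(propensity, data$X, data$A)
  mean(data$Y * (data$A == d) / pA)
}

#' Augmented inverse probability weighted value estimator
#'
#' `V_AIPWE(d) = mean( Y I{A = d}/pi{d(X); X}
#'   - [I{A = d} - pi{d(X); X}]/pi{d(X); X} * Q{X, d(X)} )`.
#' The augmentation term has mean zero when either nuisance model is
#' correct, making the estimator doubly robust; with a zero outcome model it
#' collapses to [ipwe_value()] exactly.
#'
#' @inheritParams ipwe_value
#' @param outcome Outcome model (see [aipw_weights()]).
#' @return Scalar value estimate.
#' @export
aipwe_value <- function(data, rule, propensity, outcome) {
  d <- .apply_rule(rule, data$X)
  pd <- .predict_prop(propensity, data$X, d)
  qd <- .predict_out(outcome, data$X, d)
  Id <- as.numeric(data$A == d)
  mean(data$Y * Id / pd - (Id - pd) / pd * qd)
}

#' Normalized (Hajek) IPW value estimator
#'
#' The ratio form
#' `mean(Y I{A = d}/pi) / mean(I{A = d}/pi)` used to evaluate estimated
#' rules on real data: it is invariant to rescaling of the weights and needs
#' no outcome model. Errors if no subject's treatment is concordant with the
#' rule (zero denominator).
#'
#' @inheritParams ipwe_value
#' @return Scalar value estimate.
#' @export
normalized_ipwe_value <- function(data, rule, propensity) {
  d <- .apply_rule(rule, data$X)
  pA <- .predict_prop(propensity, data$X, data$A)
  Id <- as.numeric(data$A == d)
  den <- mean(Id / pA)
  if (den <= 0)
    stop("normalized_ipwe_value: no subject concordant with the rule")
  mean(data$Y * Id / pA) / den
}

#' Weighted 0-1 misclassification risk
#'
#' The empirical risk whose minimizer (over all sign assignments) coincides
#' with the maximizer of the AIPW value:
#' `mean( |W_1| I{sgn(W_1) f(X) < 0} + |W_-1| I{-sgn(W_-1) f(X) < 0} )`,
#' with sgn(0) = +1. The surrogate-loss objective is the convex relaxation
#' of this quantity.
#'
#' @inheritParams ipwe_value
#' @param weights A `weight_set` from [aipw_weights()] or
#'   [stabilized_weights()].
#' @return Scalar risk.
#' @export
weighted_zero_one_risk <- function(data, rule, weights) {
  f <- .rule_link(rule, data$X)
  s1 <- sgn(weights$w_plus)
  sm <- sgn(weights$w_minus)
  mean(abs(weights$w_plus) * (s1 * f < 0) +
         abs(weights$w_minus) * (-sm * f < 0))
}
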