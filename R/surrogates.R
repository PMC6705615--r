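#' Convex surrogate losses and their psi transforms
#'
#' The weighted 0-1 classification objective underlying the doubly robust
#' rule estimator is non-convex; each estimator in the family replaces the
#' indicator with one of four convex, non-increasing surrogate losses:
#'
#' * hinge: `phi(t) = max(1 - t, 0)`
#' * squared hinge: `phi(t) = max(1 - t, 0)^2`
#' * logistic: `phi(t) = log(1 + exp(-t))` (natural log)
#' * exponential: `phi(t) = exp(-t)`
#'
#' Each loss carries its psi transform, the monotone map relating excess
#' surrogate risk to excess value: `psi(theta) = |theta|` (hinge),
#' `theta^2` (squared hinge),
#' `(1+theta)log(1+theta)/2 + (1-theta)log(1-theta)/2` (logistic, with the
#' convention `0*log 0 = 0`), and `1 - sqrt(1 - theta^2)` (exponential).
#' All are invertible on \[0, 1\] with monotone non-decreasing inverses;
#' a flatter psi at the origin means a looser value bound, and the hinge
#' transform is the tightest of the four.
#'
#' Numerical notes: the logistic loss is evaluated through the softplus
#' identity so large negative arguments do not overflow; the exponential
#' loss is capped at `exp(40)` (with a warning) to keep early optimizer
#' iterations finite. The logistic psi inverse has no closed form and is
#' computed by bisection to 1e-10.
#'
#' @param name One of `"logistic"`, `"hinge"`, `"sqhinge"`, `"exp"`.
#' @return An object of class `surrogate_loss`: a list with elements
#'   `name`, `phi(t)`, `grad(t)` (derivative/subgradient of phi),
#'   `psi(theta)`, `psi_inverse(u)` and logical `smooth`.
#' @examples
#' l <- surrogate_loss("logistic")
#' l$phi(0)              # log(2)
#' l$psi_inverse(l$psi(0.4))
#' @export
surrogate_loss <- function(name = c("logistic", "hinge", "sqhinge", "exp")) {
  name <- match.arg(name)
  check_theta <- function(theta) {
    if (any(theta < 0 | theta > 1))
      stop("psi: theta must lie in [0, 1]")
  }
  obj <- switch(name,
    hinge = list(
      phi = function(t) pmax(1 - t, 0),
      grad = function(t) -as.numeric(t < 1),
      smooth = FALSE,
      psi = function(theta) { check_theta(theta); abs(theta) },
      psi_inverse = function(u) {
        if (any(u < 0 | u > 1)) stop("psi_inverse: u outside range [0, 1]")
        u
      }
    ),
    sqhinge = list(
      phi = function(t) pmax(1 - t, 0)^2,
      grad = function(t) -2 * pmax(1 - t, 0),
      smooth = TRUE,
      psi = function(theta) { check_theta(theta); theta^2 },
      psi_inverse = function(u) {
        if (any(u < 0 | u > 1)) stop("psi_inverse: u outside range [0, 1]")
        sqrt(u)
      }
    ),
    logistic = list(
      phi = function(t) ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t))),
      grad = function(t) -stats::plogis(-t),
      smooth = TRUE,
      psi = function(theta) {
        check_theta(theta)
        xlx <- function(z) ifelse(z <= 0, 0, z * log(z))
        (xlx(1 + theta) + xlx(1 - theta)) / 2
      },
      psi_inverse = function(u) {
        if (any(u < 0 | u > log(2) + 1e-12))
          stop("psi_inverse: u outside range [0, log 2]")
        psi_l <- function(theta) {
          xlx <- function(z) ifelse(z <= 0, 0, z * log(z))
          (xlx(1 + theta) + xlx(1 - theta)) / 2
        }
        vapply(u, function(ui) {
          lo <- 0; hi <- 1
          while (hi - lo > 1e-10) {
            mid <- (lo + hi) / 2
            if (psi_l(mid) < ui) lo <- mid else hi <- mid
          }
          (lo + hi) / 2
        }, numeric(1))
      }
    ),
    exp = list(
      phi = function(t) {
        if (any(-t > 40)) {
          warning("exponential loss capped at exp(40)")
          t <- pmax(t, -40)
        }
        exp(-t)
      },
      grad = function(t) -exp(pmin(-t, 40)),
      smooth = TRUE,
      psi = function(theta) { check_theta(theta); 1 - sqrt(1 - theta^2) },
      psi_inverse = function(u) {
        if (any(u < 0 | u > 1)) stop("psi_inverse: u outside range [0, 1]")
        sqrt(1 - (1 - u)^2)
      }
    )
  )
  structure(c(list(name = name), obj), class = "surrogate_loss")
}

#' @export
print.surrogate_loss <- function(x, ...) {
  cat(sprintf("surrogate_loss: %s (%s)\n", x$name,
              if (x$smooth) "smooth" else "non-smooth"))
  invisible(x)
}

.as_loss <- function(loss) {
  if (inherits(loss, "surrogate_loss")) loss else surrogate_loss(loss)
}

# Huber-smoothed hinge used for the continuation scheme in the optimizer:
# C1, convex, equal to the hinge outside (1 - delta, 1).
.smoothed_hinge <- function(delta) {
  list(
    phi = function(t) {
      ifelse(t >= 1, 0,
             ifelse(t <= 1 - delta, 1 - t - delta / 2, (1 - t)^2 / (2 * delta)))
    },
    grad = function(t) {
      ifelse(t >= 1, 0, ifelse(t <= 1 - delta, -1, -(1 - t) / delta))
    }
  )
}
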