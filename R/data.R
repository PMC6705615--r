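#' Observational treatment data
#'
#' Bundles the covariate matrix, binary treatment and outcome of an
#' observational (or randomized) study into a validated container used by
#' every estimator in the package.
#'
#' @param X Numeric matrix (n x p) of baseline covariates. Columns are
#'   renamed `x1 ... xp`.
#' @param A Treatment vector of length n with entries in \{-1, +1\}.
#' @param Y Numeric outcome vector of length n, coded so that higher values
#'   are better.
#'
#' @return An object of class `itr_data`: a list with elements `X`, `A`, `Y`.
#' @examples
#' d <- itr_data(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5), rnorm(10))
#' nrow(d$X)
#' @export
itr_data <- function(X, A, Y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  A <- as.numeric(A)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n < 1L) stop("itr_data: need at least one subject")
  if (length(A) != n || length(Y) != n)
    stop("itr_data: X, A and Y must have matching lengths")
  if (anyNA(X) || anyNA(A) || anyNA(Y))
    stop("itr_data: missing values are not allowed")
  if (!all(A %in% c(-1, 1)))
    stop("itr_data: treatment A must be coded in {-1, +1}")
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, A = A, Y = Y), class = "itr_data")
}

#' @export
print.itr_data <- function(x, ...) {
  cat(sprintf("itr_data: n = %d subjects, p = %d covariates\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  treated (A = +1): %d (%.1f%%)\n",
              sum(x$A == 1), 100 * mean(x$A == 1)))
  cat(sprintf("  outcome Y: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$Y), min(x$Y), max(x$Y)))
  invisible(x)
}

#' @export
`[.itr_data` <- function(x, i, ...) {
  itr_data(x$X[i, , drop = FALSE], x$A[i], x$Y[i])
}

#' @export
as.data.frame.itr_data <- function(x, ...) {
  data.frame(x$X, a = x$A, y = x$Y)
}

#' Read/write treatment data as CSV
#'
#' The on-disk format has columns `x1 ... xp`, `a` (in \{-1, 1\}) and `y`.
#'
#' @param path File path.
#' @return `read_itr_csv` returns an [itr_data] object; `write_itr_csv`
#'   invisibly returns `path`.
#' @export
read_itr_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("a", "y") %in% names(df)))
    stop("read_itr_csv: file must have columns 'a' and 'y'")
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  itr_data(as.matrix(df[xcols]), df$a, df$y)
}

#' @rdname read_itr_csv
#' @param data An [itr_data] object.
#' @export
write_itr_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

# sign convention used throughout: sgn(0) = +1
sgn <- function(x) ifelse(x >= 0, 1, -1)

# Apply a decision rule to a covariate matrix, returning +/-1 recommendations.
# Rules may be plain functions X -> {-1,+1}, or any fitted object with a
# predict(object, X, type = "class") method (linear_rule, earl, qlearn, ...).
.apply_rule <- function(rule, X) {
  d <- if (is.function(rule)) rule(X) else stats::predict(rule, X, type = "class")
  d <- as.numeric(d)
  if (length(d) == 1L) d <- rep(d, nrow(X))
  if (length(d) != nrow(X) || !all(d %in% c(-1, 1)))
    stop("rule must return one recommendation in {-1, +1} per subject")
  d
}

# Decision-function values f(x); plain +/-1 vectors from function rules are
# valid decision values (sgn(f) = f there).
.rule_link <- function(rule, X) {
  if (is.function(rule)) as.numeric(rule(X))
  else stats::predict(rule, X, type = "link")
}
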