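# Small synthetic fixtures built in code; all randomness seeded per test.

# A dataset with hand-controllable pieces, for estimator arithmetic tests.
make_toy_data <- function(n = 50, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  A <- sample(c(-1, 1), n, replace = TRUE)
  Y <- rnorm(n)
  itr_data(X, A, Y)
}

# Constant-probability propensity as a plain function (pluggable contract).
const_prop <- function(p1) {
  force(p1)
  function(X, a) ifelse(rep_len(a, nrow(X)) == 1, p1, 1 - p1)
}

# Weight set assembled directly from vectors.
make_weights <- function(w_plus, w_minus) {
  structure(list(w_plus = w_plus, w_minus = w_minus, stabilized = FALSE),
            class = "weight_set")
}

# Exhaustive AIPWE value over every sign vector on n subjects: the brute
# force oracle for the weighted 0-1 reformulation. Returns a matrix of sign
# vectors and the value of each.
enumerate_sign_rules <- function(n) {
  G <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(G) <- NULL
  G
}
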