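test_that("objective matches its closed forms in degenerate cases", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  w0 <- make_weights(rep(0, 10), rep(0, 10))
  r <- linear_rule(0.5, c(1, -2))
  expect_equal(earl_objective(r, X, w0, "logistic", 0.3), 0.3 * 5)

  # zero rule under logistic loss: phi(0) = log 2 factors out
  w <- make_weights(rnorm(10), rnorm(10))
  r0 <- linear_rule(0, c(0, 0))
  expect_equal(earl_objective(r0, X, w, "logistic", 0),
               log(2) * mean(abs(w$w_plus) + abs(w$w_minus)))

  # symmetric single subject: minimum at f = 0
  X1 <- matrix(0, 1, 1)
  ws <- make_weights(1, 1)
  fit <- minimize_earl(X1, ws, "logistic", 0.5)
  expect_lt(abs(fit$rule$intercept), 1e-5)
})

test_that("optimizer pushes f positive when all weight favors treatment", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  w <- make_weights(runif(20, 0.5, 2), rep(0, 20))
  for (loss in c("logistic", "hinge", "sqhinge", "exp")) {
    fit <- minimize_earl(X, w, loss, 0.01)
    f <- predict(fit$rule, X, type = "link")
    expect_true(all(f > 0), info = loss)
  }
})

test_that("doubling weights at fixed lambda = halving lambda at fixed weights", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  w <- make_weights(rnorm(30), rnorm(30))
  w2 <- make_weights(2 * w$w_plus, 2 * w$w_minus)
  f1 <- minimize_earl(X, w2, "logistic", 0.2)
  f2 <- minimize_earl(X, w, "logistic", 0.1)
  expect_equal(coef(f1$rule), coef(f2$rule), tolerance = 1e-4)
})

test_that("smooth-loss solutions carry a small-gradient certificate", {
  set.seed(5)
  X <- matrix(rnorm(100), 50, 2)
  w <- make_weights(rnorm(50, 1), rnorm(50, 0.5))
  for (loss in c("logistic", "sqhinge", "exp")) {
    fit <- minimize_earl(X, w, loss, 0.1)
    expect_lt(fit$grad_norm, 1e-5)
    expect_true(fit$converged)
  }
})

test_that("objective is convex along random rule segments", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  w <- make_weights(rnorm(30), rnorm(30))
  for (loss in c("hinge", "logistic", "sqhinge", "exp")) {
    for (i in 1:25) {
      a <- rnorm(3); b <- rnorm(3)
      oa <- earl_objective(linear_rule(a[1], a[-1]), X, w, loss, 0.2)
      ob <- earl_objective(linear_rule(b[1], b[-1]), X, w, loss, 0.2)
      m <- (a + b) / 2
      om <- earl_objective(linear_rule(m[1], m[-1]), X, w, loss, 0.2)
      expect_lte(om, (oa + ob) / 2 + 1e-10)
    }
  }
})

test_that("one-dimensional fits match a dense grid-search oracle", {
  # light version of the acceptance check (logistic only)
  set.seed(7)
  X <- matrix(rnorm(20), 20, 1)
  w <- make_weights(rnorm(20, 0.5), rnorm(20, 0.2))
  fit <- minimize_earl(X, w, "logistic", 0.05)
  grid <- seq(-5, 5, length.out = 100)
  gmin <- min(outer(grid, grid, Vectorize(function(b0, b1) {
    earl_objective(linear_rule(b0, b1), X, w, "logistic", 0.05)
  })))
  expect_lte(fit$objective, gmin + 1e-8)
})

test_that("lambda selection: single-point grids, ties, determinism", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 300, seed = 30)
  ms <- model_spec(2, "CC")
  prop <- fit_propensity(d, ms)
  w <- aipw_weights(d, prop, fit_outcome(d, ms))

  sel1 <- cv_select_lambda(d, w, prop, "logistic", lambda_grid = 0.7,
                           cv_folds = 5, seed = 1)
  expect_equal(sel1$lambda, 0.7)
  expect_equal(nrow(sel1$cv_table), 1)

  # zero weights: every lambda fits the zero rule, all CV values tie,
  # and the tie breaks toward the larger penalty
  w0 <- make_weights(rep(0, 300), rep(0, 300))
  sel0 <- cv_select_lambda(d, w0, prop, "logistic",
                           lambda_grid = c(0.25, 4), cv_folds = 5, seed = 2)
  expect_equal(sel0$lambda, 4)

  sel2 <- cv_select_lambda(d, w, prop, "logistic",
                           lambda_grid = 2^(-2:2), cv_folds = 5, seed = 9)
  sel3 <- cv_select_lambda(d, w, prop, "logistic",
                           lambda_grid = 2^(-2:2), cv_folds = 5, seed = 9)
  expect_identical(sel2, sel3)
  expect_true(sel2$lambda %in% 2^(-2:2))
})

test_that("owl is exactly the hinge/zero-outcome special case of earl", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 200, seed = 31)
  prop <- fit_propensity(d, model_spec(2, "CC"))
  f_owl <- owl(d, prop, lambda = 0.5)
  f_earl <- earl(d, propensity = prop, outcome = zero_outcome(),
                 loss = "hinge", lambda = 0.5)
  expect_identical(coef(f_owl), coef(f_earl))
})

test_that("sample splitting is deterministic and aggregates by averaging", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 600, seed = 32)
  s1 <- earl_split(d, model_spec(2, "CC"), K = 2, lambda = 0.25, seed = 5)
  s2 <- earl_split(d, model_spec(2, "CC"), K = 2, lambda = 0.25, seed = 5)
  expect_identical(coef(s1), coef(s2))
  # aggregated coefficients are the mean of the per-fold rules
  cf <- sapply(s1$per_fold, function(f) coef(f$rule))
  expect_equal(unname(coef(s1)), unname(rowMeans(cf)))
  expect_true(is.finite(s1$value_bar))
})

test_that("smooth and hinge losses mostly agree on well-separated problems", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 1000, seed = 33)
  prop <- function(X, a) true_propensity(sp, X, if (a[1] == 1) 1 else -1)
  out <- function(X, a) true_q(sp, X, a)
  f_log <- earl(d, propensity = prop, outcome = out, loss = "logistic",
                lambda = 0.1)
  f_hin <- earl(d, propensity = prop, outcome = out, loss = "hinge",
                lambda = 0.1)
  set.seed(34)
  Xv <- matrix(rnorm(5000 * 10), 5000, 10)
  agree <- mean(predict(f_log, Xv) == predict(f_hin, Xv))
  expect_gte(agree, 0.95)
})
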