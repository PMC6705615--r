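test_that("AIPW weights reproduce hand-computed cases", {
  # one subject, explicit nuisance values via function plug-ins
  d <- itr_data(matrix(0, 1, 1), 1, 2)
  w <- aipw_weights(d, const_prop(0.5), function(X, a) 0)
  expect_equal(w$w_plus, 4)  # pure inverse weighting: 2 / 0.5

  # A=+1, pi(-1)=0.5, Q(.,-1)=3: W_-1 = -(0 - 0.5)/0.5 * 3 = 3
  w2 <- aipw_weights(d, const_prop(0.5),
                     function(X, a) ifelse(rep_len(a, nrow(X)) == 1, 0, 3))
  expect_equal(w2$w_minus, 3)

  # Y=3, A=+1, pi(+1)=0.25, Q(.,+1)=2: W_1 = 12 - 3*2 = 6
  d3 <- itr_data(matrix(0, 1, 1), 1, 3)
  w3 <- aipw_weights(d3, const_prop(0.25),
                     function(X, a) ifelse(rep_len(a, nrow(X)) == 1, 2, 0))
  expect_equal(w3$w_plus, 6)

  # stabilized: on-arm SW = W * pi; off-arm set to zero and flagged
  sw <- stabilized_weights(d3, const_prop(0.25),
                           function(X, a) ifelse(rep_len(a, nrow(X)) == 1, 2, 0))
  expect_equal(sw$w_plus, 1.5)
  expect_equal(sw$w_minus, 0)
  expect_true(sw$off_arm_zeroed)

  # stabilized with zero Q on the observed arm reduces to Y
  sw0 <- stabilized_weights(d3, const_prop(0.25), zero_outcome())
  expect_equal(sw0$w_plus, 3)
})

test_that("value estimators agree with hand arithmetic", {
  # two subjects: (Y=1, A=+1), (Y=2, A=-1); rule recommends +1 for both
  d <- itr_data(matrix(0, 2, 1), c(1, -1), c(1, 2))
  rule_plus <- function(X) rep(1, nrow(X))
  expect_equal(ipwe_value(d, rule_plus, const_prop(0.5)), 1)  # (2 + 0)/2
  expect_equal(normalized_ipwe_value(d, rule_plus, const_prop(0.5)), 1)

  # single subject AIPWE: 4 - (0.5/0.5)*1 = 3
  d1 <- itr_data(matrix(0, 1, 1), 1, 2)
  q1 <- function(X, a) ifelse(rep_len(a, nrow(X)) == 1, 1, 0)
  expect_equal(aipwe_value(d1, rule_plus, const_prop(0.5), q1), 3)

  # everyone concordant with constant propensity: sample mean of Y
  dc <- itr_data(matrix(0, 4, 1), rep(1, 4), c(1, 2, 3, 6))
  expect_equal(normalized_ipwe_value(dc, rule_plus, const_prop(0.3)), 3)
  # no subject concordant: IPWE 0, normalized errors
  rule_minus <- function(X) rep(-1, nrow(X))
  expect_equal(ipwe_value(dc, rule_minus, const_prop(0.3)), 0)
  expect_error(normalized_ipwe_value(dc, rule_minus, const_prop(0.3)),
               "concordant")
})

test_that("AIPWE collapses to IPWE exactly under a zero outcome model", {
  for (i in 1:25) {
    d <- make_toy_data(40, 4, seed = 100 + i)
    prop <- const_prop(0.3 + 0.4 * (i %% 2))
    rule <- function(X) sgn(X[, 1] - X[, 2])
    expect_identical(aipwe_value(d, rule, prop, zero_outcome()),
                     ipwe_value(d, rule, prop))
  }
})

test_that("weighted 0-1 risk evaluates the displayed sum", {
  d <- itr_data(matrix(1, 1, 1), 1, 0)
  w <- make_weights(2, 0)
  expect_equal(weighted_zero_one_risk(d, function(X) rep(1, 1), w), 0)
  expect_equal(weighted_zero_one_risk(d, function(X) rep(-1, 1), w), 2)
  w0 <- make_weights(rep(0, 1), rep(0, 1))
  expect_equal(weighted_zero_one_risk(d, function(X) rep(-1, 1), w0), 0)

  # negative weight flips the penalized side
  wn <- make_weights(-3, 0)
  expect_equal(weighted_zero_one_risk(d, function(X) rep(1, 1), wn), 3)
  expect_equal(weighted_zero_one_risk(d, function(X) rep(-1, 1), wn), 0)
})

test_that("maximizing AIPWE equals minimizing the weighted 0-1 risk (n=6)", {
  d <- make_toy_data(6, 2, seed = 42)
  prop <- const_prop(0.4)
  om <- function(X, a) 0.3 * X[, 1] + 0.1 * rep_len(a, nrow(X))
  w <- aipw_weights(d, prop, om)
  G <- enumerate_sign_rules(6)
  vals <- apply(G, 1, function(dvec) {
    aipwe_value(d, function(X) dvec, prop, om)
  })
  risks <- apply(G, 1, function(dvec) {
    weighted_zero_one_risk(d, function(X) dvec, w)
  })
  expect_identical(which(vals >= max(vals) - 1e-10),
                   which(risks <= min(risks) + 1e-10))
  # and value + risk is constant across rules (the two objectives differ
  # by a rule-free constant)
  expect_lt(diff(range(vals + risks)), 1e-10)
})

test_that("double robustness of the AIPWE value for a fixed rule", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 10000, seed = 77)
  rule <- function(X) sgn(X[, 1])
  v_true <- true_value(sp, rule, n_mc = 4e5, seed = 78)
  for (which in c("CC", "CI", "IC")) {
    ms <- model_spec(2, which)
    prop <- fit_propensity(d, ms)
    out <- fit_outcome(d, ms)
    v <- aipwe_value(d, rule, prop, out)
    # 3 x (sampling SE of the AIPWE at n=1e4, sd of contributions ~ 12)
    expect_lt(abs(v - v_true), 3 * 12 / sqrt(10000),
              label = sprintf("AIPWE under %s", which))
  }
})

test_that("weights center on the Q-function under correct nuisances", {
  sp <- scenario_spec(2)
  d <- simulate_scenario(sp, 40000, seed = 90)
  prop <- function(X, a) true_propensity(sp, X, if (a[1] == 1) 1 else -1)
  out <- function(X, a) true_q(sp, X, a)
  w <- aipw_weights(d, prop, out)
  # E(W_a | X) = Q(X, a): compare bin means over quartiles of the contrast
  bins <- cut(d$X[, 1] + d$X[, 2], quantile(d$X[, 1] + d$X[, 2], 0:4 / 4),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    se <- sd(w$w_plus[idx]) / sqrt(sum(idx))
    expect_lt(abs(mean(w$w_plus[idx]) - mean(true_q(sp, d$X[idx, ], 1))),
              4 * se)
  }
})
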