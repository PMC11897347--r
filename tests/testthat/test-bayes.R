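test_that("beta-binomial update is the conjugate posterior", {
  p <- beta_binomial_update(2, 26)
  expect_equal(c(p$alpha, p$beta), c(3, 25))
  expect_equal(unclass(beta_binomial_update(0, 0))[c("alpha", "beta")],
               list(alpha = 1, beta = 1))    # prior returned unchanged
  p <- beta_binomial_update(6, 26)
  expect_equal(c(p$alpha, p$beta), c(7, 21))
  expect_error(beta_binomial_update(5, 4), "exceed")
  expect_error(beta_binomial_update(1, 2, a0 = 0), "positive")
})

test_that("batch and sequential beta updates agree (conjugacy)", {
  outcomes <- c(1, 0, 0, 1, 0, 1, 1, 0, 0, 0)
  batch <- beta_binomial_update(sum(outcomes), length(outcomes))
  seq_post <- Reduce(function(prior, y)
    beta_binomial_update(y, 1, a0 = prior$alpha, b0 = prior$beta),
    outcomes, init = list(alpha = 1, beta = 1))
  expect_equal(batch$alpha, seq_post$alpha)
  expect_equal(batch$beta, seq_post$beta)
})

test_that("posterior summaries use the median and equal tails", {
  s <- summarise_beta(beta_binomial_update(2, 26))
  expect_equal(round(100 * c(s$point, s$ci_low, s$ci_high), 1),
               c(9.8, 2.4, 24.3))
  # Beta(a, 1) has median 0.5^(1/a) in closed form
  for (a in c(1, 4, 10)) {
    s <- summarise_beta(structure(list(alpha = a, beta = 1),
                                  class = "beta_posterior"))
    expect_equal(s$point, 0.5^(1 / a), tolerance = 1e-12)
  }
  expect_equal(round(summarise_beta(structure(list(alpha = 4, beta = 1),
                                              class = "beta_posterior"))$point, 4),
               0.8409)
  # interval brackets the point and the posterior mean for skewed cases
  p <- beta_binomial_update(1, 40)
  s <- summarise_beta(p)
  expect_lt(s$ci_low, s$point)
  expect_gt(s$ci_high, p$alpha / (p$alpha + p$beta))
})

test_that("exceedance probabilities match the exact binomial-tail identity", {
  # P(Beta(a, b) > x) = P(Binomial(a + b - 1, x) <= a - 1) for integer a, b:
  # enumerate the lower binomial tail explicitly as the oracle
  binom_lower_tail <- function(a, b, x) {
    n <- a + b - 1
    k <- seq_len(a) - 1
    sum(choose(n, k) * x^k * (1 - x)^(n - k))
  }
  for (ab in list(c(3, 25), c(7, 21), c(1, 1), c(5, 2))) {
    for (x in c(0.1, 0.3, 0.7)) {
      s <- summarise_beta(structure(list(alpha = ab[1], beta = ab[2]),
                                    class = "beta_posterior"), threshold = x)
      expect_equal(s$prob_exceeds, binom_lower_tail(ab[1], ab[2], x),
                   tolerance = 1e-12)
    }
  }
  s <- summarise_beta(beta_binomial_update(6, 26), threshold = 0.30)
  expect_equal(round(s$prob_exceeds, 3), 0.256)
  # degenerate thresholds
  p <- beta_binomial_update(3, 10)
  expect_equal(summarise_beta(p, threshold = 0)$prob_exceeds, 1)
  expect_equal(summarise_beta(p, threshold = 1)$prob_exceeds, 0)
})

test_that("beta quantiles agree with a Monte-Carlo oracle", {
  set.seed(4002)
  p <- beta_binomial_update(6, 26)
  draws <- rbeta(1e7, p$alpha, p$beta)
  s <- summarise_beta(p)
  for (q in list(c(0.025, s$ci_low), c(0.5, s$point), c(0.975, s$ci_high))) {
    emp <- unname(quantile(draws, q[1]))
    # SE of an empirical quantile: sqrt(q(1-q)/n) / density at the quantile
    se <- sqrt(q[1] * (1 - q[1]) / 1e7) / dbeta(q[2], p$alpha, p$beta)
    expect_lt(abs(emp - q[2]), 3 * se)
  }
})

test_that("exponential-IG update accumulates events and follow-up time", {
  g <- exponential_ig_update(numeric(0), logical(0))
  expect_equal(c(g$shape, g$rate_total), c(0.001, 0.001))  # prior unchanged
  g <- exponential_ig_update(c(2, 4, 6), c(TRUE, TRUE, TRUE))
  expect_equal(c(g$shape, g$rate_total), c(3.001, 12.001))
  g <- exponential_ig_update(c(2, 4, 6), c(TRUE, TRUE, FALSE))
  expect_equal(c(g$shape, g$rate_total), c(2.001, 12.001))
  expect_error(exponential_ig_update(c(2, 0), c(TRUE, TRUE)), "positive")
  # conjugacy: batch equals sequential
  times <- c(3.2, 1.1, 7.5, 2.2)
  events <- c(TRUE, FALSE, TRUE, TRUE)
  batch <- exponential_ig_update(times, events)
  seq_post <- list(shape = 0.001, rate_total = 0.001)
  for (i in seq_along(times))
    seq_post <- exponential_ig_update(times[i], events[i],
                                      a0 = seq_post$shape,
                                      b0 = seq_post$rate_total)
  expect_equal(batch$shape, seq_post$shape)
  expect_equal(batch$rate_total, seq_post$rate_total)
})

test_that("median-survival summary transforms the hazard posterior correctly", {
  # concentration limit: shape/rate_total = 0.1 with huge shape -> ln2/0.1
  g <- structure(list(shape = 1e7, rate_total = 1e8), class = "surv_posterior")
  s <- summarise_median_survival(g)
  expect_equal(s$point, log(2) / 0.1, tolerance = 1e-3)
  # scale equivariance: doubling all times doubles every summary component
  t1 <- c(5, 9, 13, 21)
  ev <- c(TRUE, TRUE, FALSE, TRUE)
  s1 <- summarise_median_survival(exponential_ig_update(t1, ev))
  s2 <- summarise_median_survival(exponential_ig_update(2 * t1, ev))
  expect_equal(2 * s1$point, s2$point, tolerance = 1e-3)
  expect_equal(2 * s1$ci_low, s2$ci_low, tolerance = 1e-3)
  expect_equal(2 * s1$ci_high, s2$ci_high, tolerance = 1e-3)
  expect_true(s1$ci_low <= s1$point && s1$point <= s1$ci_high)
})

test_that("median-survival quantiles agree with a Monte-Carlo oracle", {
  set.seed(4003)
  g <- exponential_ig_update(rexp(40, 0.2), rep(TRUE, 40))
  s <- summarise_median_survival(g)
  lambda <- rgamma(1e6, shape = g$shape, rate = g$rate_total)
  m_draws <- log(2) / lambda
  for (q in list(c(0.025, s$ci_low), c(0.5, s$point), c(0.975, s$ci_high))) {
    emp <- unname(quantile(m_draws, q[1]))
    expect_equal(emp, q[2], tolerance = 0.01)
  }
})
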