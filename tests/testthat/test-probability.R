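test_that("closed-form corners are exact", {
  expect_identical(event_probability(10, 0.5, wemc_event("eq", 0)), 2^-10)
  expect_equal(event_probability(297, 0.475, wemc_event("le", 297)), 1)
  expect_equal(event_probability(297, 0.475, wemc_event("ge", 0)), 1)
  expect_equal(event_probability(297, 0.475, wemc_event("eq", 400)), 0)
  expect_equal(event_probability(297, 0.475, wemc_event("between", 400, 500)), 0)
})

test_that("event probabilities match exhaustive Bernoulli enumeration for n <= 12", {
  for (n in c(5, 12)) {
    for (p in c(0.3, 0.7)) {
      pmf <- enumerate_sum_pmf(tibble::tibble(n = n, p = p))
      for (k in 0:n) {
        expect_equal(event_probability(n, p, wemc_event("eq", k)),
                     pmf[k + 1], tolerance = 1e-12)
        expect_equal(event_probability(n, p, wemc_event("le", k)),
                     sum(pmf[1:(k + 1)]), tolerance = 1e-12)
      }
      expect_equal(event_probability(n, p, wemc_event("between", 2, n - 1)),
                   sum(pmf[3:n]), tolerance = 1e-12)
    }
  }
})

test_that("complement identity and pmf normalization hold", {
  for (spec in list(c(297, 0.475), c(50, 0.02), c(2000, 0.7))) {
    n <- spec[1]; p <- spec[2]
    for (k in unique(round(seq(0, n - 1, length.out = 25)))) {
      expect_equal(event_probability(n, p, wemc_event("le", k)) +
                     event_probability(n, p, wemc_event("ge", k + 1)),
                   1, tolerance = 1e-12)
    }
    total <- sum(vapply(0:n, function(k) {
      event_probability(n, p, wemc_event("eq", k))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("deep-tail intervals survive cdf cancellation via log-space summation", {
  v <- event_probability(297, 0.478, wemc_event("between", 47, 94))
  direct <- exp(wemc:::log_sum_exp(dbinom(47:94, 297, 0.478, log = TRUE)))
  expect_gt(v, 0)
  expect_equal(v, direct, tolerance = 1e-10)
})

test_that("strict and non-strict inequalities differ by the boundary atom", {
  p_le <- event_probability(297, 0.475, wemc_event("le", 141))
  p_lt <- event_probability(297, 0.475, wemc_event("lt", 141))
  expect_equal(p_le - p_lt, dbinom(141, 297, 0.475), tolerance = 1e-12)
})

test_that("joint probability multiplies marginals, optionally 2-dp rounded", {
  e1 <- list(n = 297, p = 0.431, event = wemc_event("gt", 130))
  e2 <- list(n = 297, p = 0.498, event = wemc_event("gt", 130))
  expect_equal(joint_probability(list(e1)),
               event_probability(297, 0.431, e1$event))
  expect_equal(joint_probability(list(e1, e2)),
               event_probability(297, 0.431, e1$event) *
                 event_probability(297, 0.498, e2$event))
  expect_equal(joint_probability(list(e1, e2), rounding = "two_dp_marginals"),
               0.38 * 0.98)
  expect_error(joint_probability(list()), "empty")
})

test_that("conditional probability equals the marginal under independence", {
  target <- list(n = 297, p = 0.478, event = wemc_event("eq", 140))
  given <- list(n = 297, p = 0.431, event = wemc_event("ge", 0))
  expect_equal(conditional_probability(target, given),
               dbinom(140, 297, 0.478))
  impossible <- list(n = 297, p = 0.431, event = wemc_event("between", 400, 500))
  expect_error(conditional_probability(target, impossible), "probability 0")
})

test_that("the query grammar parses single, interval, and joint events", {
  est <- tibble::tibble(cause = c("C1", "C7"), n = 297, p_hat = c(0.475, 0.498))
  res <- query_probabilities(est, c("C1=141", "138<=C7<=158", "C1>=141,C7<=148"))
  expect_equal(res$probability[1], dbinom(141, 297, 0.475))
  expect_equal(res$probability[2],
               pbinom(158, 297, 0.498) - pbinom(137, 297, 0.498))
  expect_equal(res$probability[3],
               pbinom(140, 297, 0.475, lower.tail = FALSE) *
                 pbinom(148, 297, 0.498))
  # strict interval bounds are exclusive
  strict <- query_probabilities(est, "138<C7<158")$probability
  expect_equal(strict, pbinom(157, 297, 0.498) - pbinom(138, 297, 0.498))
  expect_error(query_probabilities(est, "C9=3"), "unknown cause")
  expect_error(query_probabilities(est, "C1~3"), "cannot parse")
  expect_error(wemc_event("between", 10, 5), "lower > upper")
})
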