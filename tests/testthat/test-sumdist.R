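test_that("tiny convolutions match hand-computable distributions", {
  d <- exact_sum_distribution(tibble::tibble(n = c(2, 1), p = 0.5))
  expect_equal(d$pmf, c(1, 3, 3, 1) / 8, tolerance = 1e-15)
  expect_equal(d$cdf[4], 1, tolerance = 1e-12)
})

test_that("identical components pool to a single binomial", {
  d <- exact_sum_distribution("50:0.5x5")
  expect_equal(d$pmf, dbinom(0:250, 250, 0.5), tolerance = 1e-12)
  d2 <- exact_sum_distribution("20:0.3x3")
  expect_equal(d2$pmf, dbinom(0:60, 60, 0.3), tolerance = 1e-12)
})

test_that("heterogeneous convolution matches exhaustive 2^9 enumeration", {
  comp <- tibble::tibble(n = c(3, 4, 2), p = c(0.2, 0.7, 0.5))
  d <- exact_sum_distribution(comp)
  expect_equal(d$pmf, enumerate_sum_pmf(comp), tolerance = 1e-12)
})

test_that("component order does not change the pmf", {
  a <- exact_sum_distribution(tibble::tibble(n = c(10, 25, 4),
                                             p = c(0.1, 0.6, 0.9)))
  b <- exact_sum_distribution(tibble::tibble(n = c(4, 10, 25),
                                             p = c(0.9, 0.1, 0.6)))
  expect_equal(a$pmf, b$pmf, tolerance = 1e-12)
})

test_that("pmf normalizes and matches the moment identities", {
  comp <- tibble::tibble(n = c(297, 297, 297), p = c(0.475, 0.683, 0.431))
  d <- exact_sum_distribution(comp)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
  expect_true(all(diff(d$cdf) >= -1e-12))
  expect_equal(sum(d$support * d$pmf), sum(comp$n * comp$p), tolerance = 1e-8)
  mu <- sum(comp$n * comp$p)
  expect_equal(sum((d$support - mu)^2 * d$pmf),
               sum(comp$n * comp$p * (1 - comp$p)), tolerance = 1e-8)
})

test_that("the support cap redirects to the saddlepoint method", {
  expect_error(exact_sum_distribution(tibble::tibble(n = 2e5, p = 0.5)),
               "saddlepoint")
})

test_that("saddlepoint pmf and tails track the exact distribution closely", {
  expect_equal(saddlepoint_sum("50:0.6x5", 100, "pmf"),
               dbinom(100, 250, 0.6), tolerance = 0.02)
  expect_equal(saddlepoint_sum("50:0.5x5", 125, "le"),
               pbinom(125, 250, 0.5), tolerance = 0.01)
  # integer-mean case exercises the near-mean limit branch
  v <- saddlepoint_sum("50:0.5x5", 125, "ge")
  expect_true(is.finite(v))
  expect_equal(v, pbinom(124, 250, 0.5, lower.tail = FALSE), tolerance = 0.01)
})

test_that("saddlepoint relative error stays under 5% across heterogeneous grids", {
  cases <- list(
    tibble::tibble(n = c(50, 120, 330), p = c(0.1, 0.45, 0.8)),
    tibble::tibble(n = c(297, 297), p = c(0.475, 0.683)),
    tibble::tibble(n = rep(40, 10), p = seq(0.05, 0.95, length.out = 10))
  )
  for (comp in cases) {
    d <- exact_sum_distribution(comp)
    # reverse-accumulated upper tail: 1 - cdf underflows at 1e-16
    ge_exact <- rev(cumsum(rev(d$pmf)))
    keep <- d$pmf > 1e-300 & d$support > 0 & d$support < sum(comp$n)
    ts <- d$support[keep]
    ts <- ts[unique(round(seq(1, length(ts), length.out = 40)))]
    for (t in ts) {
      approx_pmf <- saddlepoint_sum(comp, t, "pmf")
      expect_lt(abs(approx_pmf - d$pmf[t + 1]) / d$pmf[t + 1], 0.05)
      if (ge_exact[t + 1] > 1e-300) {
        approx_ge <- saddlepoint_sum(comp, t, "ge")
        expect_lt(abs(approx_ge - ge_exact[t + 1]) / ge_exact[t + 1], 0.05)
      }
    }
  }
})

test_that("degenerate and out-of-support inputs are handled", {
  expect_error(saddlepoint_sum(tibble::tibble(n = 5, p = 1), 3, "pmf"),
               "degenerate")
  expect_equal(saddlepoint_sum("10:0.4x2", 25, "pmf"), 0)
  expect_equal(saddlepoint_sum("10:0.4x2", -1, "le"), 0)
  expect_equal(saddlepoint_sum("10:0.4x2", 0, "ge"), 1)
  # boundary points use the exact closed form
  expect_equal(saddlepoint_sum("10:0.4x2", 0, "pmf"), 0.6^20, tolerance = 1e-12)
  expect_equal(saddlepoint_sum("10:0.4x2", 20, "pmf"), 0.4^20, tolerance = 1e-12)
})

test_that("sum_event_probability routes events through either method", {
  comp <- "50:0.5x5"
  expect_equal(sum_event_probability(comp, wemc_event("eq", 100)),
               dbinom(100, 250, 0.5), tolerance = 1e-12)
  expect_equal(sum_event_probability(comp, wemc_event("le", 120)),
               pbinom(120, 250, 0.5), tolerance = 1e-12)
  expect_equal(sum_event_probability(comp, wemc_event("between", 110, 130)),
               pbinom(130, 250, 0.5) - pbinom(109, 250, 0.5),
               tolerance = 1e-12)
  expect_equal(sum_event_probability(comp, wemc_event("eq", 260)), 0)
  sp <- sum_event_probability(comp, wemc_event("ge", 130),
                              method = "saddlepoint")
  expect_equal(sp, pbinom(129, 250, 0.5, lower.tail = FALSE), tolerance = 0.02)
  sp_between <- sum_event_probability(comp, wemc_event("between", 110, 130),
                                      method = "saddlepoint")
  expect_equal(sp_between, pbinom(130, 250, 0.5) - pbinom(109, 250, 0.5),
               tolerance = 0.02)
})

test_that("component spec strings parse with repetition", {
  comp <- binomial_components("50:0.5x5")
  expect_equal(nrow(comp), 5)
  comp2 <- binomial_components("297:0.475,297:0.683")
  expect_equal(comp2$p, c(0.475, 0.683))
  expect_error(binomial_components("50:1.5"), "in \\[0, 1\\]")
  expect_error(binomial_components("0:0.5"), "positive integers")
  expect_error(binomial_components("junk"), "cannot parse")
})
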