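test_that("indicators follow the strict-exceedance rule with ties as zero", {
  em <- build_exceedance(make_panel(A = c(5, 7, 7, 6)))
  expect_equal(em$A, c(1L, 0L, 0L))
  em2 <- build_exceedance(make_panel(A = c(1, 2, 3, 4)))
  expect_equal(em2$A, c(1L, 1L, 1L))
  expect_error(build_exceedance(make_panel(A = 5)), "at least 2 weeks")
})

test_that("a combined panel yields one fewer row, with segment tags", {
  cfg <- simulation_config(194, c("A", "B"), c(400, 900),
                           yearly_amplitude = 0.1, dispersion = 50, seed = 2)
  obs <- simulate_panel(cfg)
  fc <- forecast_panel(fit_forecaster(obs), horizon = 104)
  em <- build_exceedance(combine_panels(obs, fc))
  expect_equal(nrow(em), 297)
  expect_equal(sum(em$segment == "observed"), 193)
  expect_equal(sum(em$segment == "boundary"), 1)
  expect_equal(sum(em$segment == "forecast"), 103)
})

test_that("combining rejects gaps, overlaps, and label mismatches", {
  obs <- make_panel(A = c(1, 2, 3))
  gap <- make_panel(A = c(4, 5), start = week0 + 7 * 4)
  expect_error(combine_panels(obs, gap), "7 days")
  wrong <- make_panel(B = c(4, 5), start = week0 + 7 * 3)
  expect_error(combine_panels(obs, wrong), "labels differ")
  ok <- make_panel(A = c(4, 5), start = week0 + 7 * 3)
  expect_equal(nrow(combine_panels(obs, ok)), 5)
})

test_that("indicators are invariant to shifting and positive scaling of counts", {
  withr::local_seed(7)
  counts <- matrix(rpois(60, 50), ncol = 2,
                   dimnames = list(NULL, c("A", "B")))
  base <- build_exceedance(make_panel(A = counts[, 1], B = counts[, 2]))
  shifted <- build_exceedance(make_panel(A = counts[, 1] + 17,
                                         B = counts[, 2] + 17))
  scaled <- build_exceedance(make_panel(A = counts[, 1] * 3,
                                        B = counts[, 2] * 3))
  expect_identical(base$A, shifted$A)
  expect_identical(base$B, scaled$B)
})

test_that("WCMI estimates are column proportions at full precision", {
  ind <- c(rep(1, 141), rep(0, 156))
  em <- build_exceedance(panel_from_indicators(matrix(ind, ncol = 1,
                                                      dimnames = list(NULL, "A"))))
  est <- estimate_wcmi(em)
  expect_equal(est$n, 297)
  expect_equal(est$ones, 141)
  expect_equal(est$p_hat, 141 / 297)
  expect_equal(estimate_wcmi(em, round_digits = 3)$p_hat, 0.475)
  allones <- estimate_wcmi(build_exceedance(panel_from_indicators(
    matrix(1, 297, 1, dimnames = list(NULL, "A")))))
  expect_equal(allones$p_hat, 1)
  # conservation: total ones across causes equals total matrix mass
  withr::local_seed(11)
  m <- matrix(rbinom(297 * 4, 1, 0.5), ncol = 4,
              dimnames = list(NULL, paste0("C", 1:4)))
  em4 <- build_exceedance(panel_from_indicators(m))
  expect_equal(sum(estimate_wcmi(em4)$ones), sum(m))
})

test_that("the proportion estimator is unbiased on i.i.d. indicator columns", {
  withr::local_seed(19)
  means <- replicate(500, {
    m <- matrix(rbinom(297, 1, 0.6), ncol = 1, dimnames = list(NULL, "A"))
    estimate_wcmi(build_exceedance(panel_from_indicators(m)))$p_hat
  })
  expect_lt(abs(mean(means) - 0.6), 0.01)
})

test_that("homogeneous exceedance counts give a null chi-square and V = 0", {
  m <- cbind(A = c(rep(1, 10), rep(0, 20)), B = c(rep(0, 20), rep(1, 10)))
  res <- independence_test(build_exceedance(panel_from_indicators(m)))
  expect_equal(res$statistic, 0)
  expect_equal(res$cramers_v, 0)
  expect_equal(res$df, 1)
})

test_that("chi-square core matches the textbook statistic on a 2x2 table", {
  # causes with 10/30 and 20/30 exceedances -> table [[10,20],[20,10]];
  # hand computation sum((o-e)^2/e) with all e = 15 gives 4*25/15 = 6.6667
  m <- cbind(A = c(rep(1, 10), rep(0, 20)), B = c(rep(1, 20), rep(0, 10)))
  res <- independence_test(build_exceedance(panel_from_indicators(m)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-6)
  expect_equal(res$cramers_v, sqrt((20 / 3) / 60), tolerance = 1e-6)
  td <- tidy(res)
  expect_equal(td$exceed, c(10, 20))
  gl <- glance(res)
  expect_named(gl, c("statistic", "df", "p_value", "cramers_v"))
})

test_that("degenerate tables are rejected", {
  m <- matrix(1, 20, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(independence_test(build_exceedance(panel_from_indicators(m))),
               "degenerate")
})

test_that("exceedance matrices round-trip through CSV", {
  m <- matrix(rbinom(40, 1, 0.5), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  em <- build_exceedance(panel_from_indicators(m))
  f <- withr::local_tempfile(fileext = ".csv")
  write_exceedance(em, f)
  back <- read_exceedance(f)
  expect_equal(back$A, em$A)
  expect_equal(back$segment, em$segment)
})
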