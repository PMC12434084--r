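#' Configure a synthetic weekly mortality panel
#'
#' Describes a CDC-like multivariate weekly count process: per-cause
#' expected counts follow a linear trend modulated by a yearly sinusoid,
#' marginal counts are negative binomial (gamma-mixed Poisson; real
#' mortality series are overdispersed), and causes are coupled through a
#' Gaussian copula on the latent uniforms so cross-cause correlation is
#' configurable without distorting the marginals.
#'
#' The expected count for cause k at week t (t = 0, 1, ...) is
#' `(baseline_k + trend_k * t) * (1 + yearly_amplitude_k *
#' sin(2 * pi * (t - yearly_phase_k) / 52.1775))`; the yearly period is
#' fixed at 365.25 / 7 weeks.
#'
#' @param n_weeks Number of weeks (>= 2).
#' @param causes Character vector of cause labels.
#' @param baseline Per-cause expected count at week 0 (positive; recycled).
#' @param trend Per-cause additive change in expected count per week.
#' @param yearly_amplitude Per-cause relative seasonal amplitude (>= 0).
#' @param yearly_phase Per-cause phase shift in weeks.
#' @param cross_correlation K x K symmetric positive-semidefinite latent
#'   correlation matrix with unit diagonal (default identity).
#' @param dispersion Per-cause negative-binomial size parameter (positive;
#'   larger means closer to Poisson; `Inf` gives exactly Poisson margins).
#' @param start_date First week-ending date.
#' @param seed Integer seed; all randomness in [simulate_panel()] flows
#'   from it and the caller's random state is left untouched.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_weeks,
                              causes,
                              baseline,
                              trend = 0,
                              yearly_amplitude = 0,
                              yearly_phase = 0,
                              cross_correlation = NULL,
                              dispersion = Inf,
                              start_date = as.Date("2020-01-04"),
                              seed = 1L) {
  k <- length(causes)
  if (k < 1 || anyDuplicated(causes)) abort("causes must be unique labels")
  if (n_weeks < 2) abort("n_weeks must be at least 2 (one exceedance pair)")
  rec <- function(v, what) {
    if (!length(v) %in% c(1L, k)) {
      abort(paste0("`", what, "` must have length 1 or ", k))
    }
    rep_len(as.numeric(v), k)
  }
  baseline <- rec(baseline, "baseline")
  trend <- rec(trend, "trend")
  yearly_amplitude <- rec(yearly_amplitude, "yearly_amplitude")
  yearly_phase <- rec(yearly_phase, "yearly_phase")
  dispersion <- rec(dispersion, "dispersion")
  if (any(baseline <= 0)) abort("baseline must be positive")
  if (any(yearly_amplitude < 0)) abort("yearly_amplitude must be >= 0")
  if (any(dispersion <= 0)) abort("dispersion must be positive")
  if (is.null(cross_correlation)) cross_correlation <- diag(k)
  cross_correlation <- as.matrix(cross_correlation)
  if (!all(dim(cross_correlation) == k) ||
      max(abs(cross_correlation - t(cross_correlation))) > 1e-8 ||
      max(abs(diag(cross_correlation) - 1)) > 1e-8) {
    abort("cross_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(cross_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("cross_correlation is not positive semidefinite")
  }
  structure(
    list(n_weeks = as.integer(n_weeks), causes = causes,
         baseline = baseline, trend = trend,
         yearly_amplitude = yearly_amplitude, yearly_phase = yearly_phase,
         cross_correlation = cross_correlation, dispersion = dispersion,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

weeks_per_year <- 365.25 / 7

sim_mean_curve <- function(config) {
  t <- seq_len(config$n_weeks) - 1
  k <- length(config$causes)
  mu <- vapply(seq_len(k), function(j) {
    (config$baseline[j] + config$trend[j] * t) *
      (1 + config$yearly_amplitude[j] *
         sin(2 * pi * (t - config$yearly_phase[j]) / weeks_per_year))
  }, numeric(config$n_weeks))
  if (any(mu <= 0)) {
    abort("configured mean curve is nonpositive; reduce trend or amplitude")
  }
  mu
}

#' Simulate a correlated weekly mortality count panel
#'
#' Draws a `mortality_panel` from a [simulation_config()]: latent
#' standard-normal vectors with the configured correlation matrix are
#' mapped through the normal CDF to uniforms, and each cause's uniform is
#' inverted through its negative-binomial (or Poisson, when dispersion is
#' infinite) quantile function at that week's expected count. Identical
#' configs give bitwise-identical panels.
#'
#' @param config A `simulation_config`.
#' @return A `mortality_panel` of `n_weeks` rows.
#' @examples
#' cfg <- simulation_config(52, c("A", "B"), baseline = c(400, 900),
#'                          yearly_amplitude = 0.1, seed = 42)
#' panel <- simulate_panel(cfg)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mu <- sim_mean_curve(config)
  n <- config$n_weeks
  k <- length(config$causes)
  # eigen square root admits PSD-singular correlation matrices
  e <- eigen(config$cross_correlation, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- withr::with_seed(config$seed, matrix(rnorm(n * k), n, k)) %*% rt
  u <- pnorm(z)
  counts <- vapply(seq_len(k), function(j) {
    if (is.infinite(config$dispersion[j])) {
      qpois(u[, j], lambda = mu[, j])
    } else {
      qnbinom(u[, j], size = config$dispersion[j], mu = mu[, j])
    }
  }, numeric(n))
  out <- tibble::tibble(week_ending_date = config$start_date + 7 * (0:(n - 1)))
  out[config$causes] <- as.data.frame(counts)
  as_mortality_panel(out)
}
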