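#' Fit a per-cause harmonic seasonal forecaster
#'
#' Phase I of the pipeline. Each cause's weekly count series is fitted
#' independently by ordinary least squares against an intercept, a linear
#' time trend, and `fourier_order` pairs of yearly sine/cosine harmonics
#' (period 365.25 / 7 = 52.1775 weeks by default). This is the linear
#' trend + Fourier yearly-seasonality model class that additive seasonal
#' forecasters such as Prophet use, without changepoints, so fits and
#' forecasts are deterministic.
#'
#' With `scale = "log1p"` the model is fitted to `log1p(count)` and
#' forecasts are back-transformed with `expm1`, guaranteeing nonnegative
#' forecasts; the default fits counts directly and (optionally) floors
#' forecasts at zero.
#'
#' @param panel A `mortality_panel` of observed counts.
#' @param horizon Default forecast length in weeks.
#' @param fourier_order Number of yearly harmonic pairs (>= 1).
#' @param period_weeks Seasonal period in weeks.
#' @param scale `"identity"` or `"log1p"`.
#' @param clip_negative Floor identity-scale forecasts at 0.
#' @return A `wemc_forecaster` with per-cause coefficient vectors of
#'   length `2 + 2 * fourier_order`.
#' @examples
#' cfg <- simulation_config(194, c("A", "B"), baseline = c(400, 900),
#'                          yearly_amplitude = 0.1, seed = 7)
#' fit <- fit_forecaster(simulate_panel(cfg))
#' fc <- forecast_panel(fit, horizon = 104)
#' @export
fit_forecaster <- function(panel,
                           horizon = 104,
                           fourier_order = 10,
                           period_weeks = 365.25 / 7,
                           scale = c("identity", "log1p"),
                           clip_negative = TRUE) {
  validate_panel(panel)
  scale <- match.arg(scale)
  if (horizon < 1) abort("horizon must be >= 1")
  if (fourier_order < 1) abort("fourier_order must be >= 1")
  p <- 2 + 2 * fourier_order
  if (nrow(panel) < 2 * p) {
    abort(paste0("need at least ", 2 * p, " weeks to fit ", fourier_order,
                 " harmonics; got ", nrow(panel)))
  }
  t_idx <- seq_len(nrow(panel)) - 1
  X <- fourier_design(t_idx, fourier_order, period_weeks)
  y <- panel_counts(panel)
  if (scale == "log1p") y <- log1p(y)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    abort("rank-deficient harmonic design; reduce fourier_order")
  }
  coefs <- matrix(fit$coefficients, ncol = ncol(y),
                  dimnames = list(colnames(X), cause_labels(panel)))
  structure(
    list(coefficients = coefs,
         config = list(horizon = as.integer(horizon),
                       fourier_order = as.integer(fourier_order),
                       period_weeks = period_weeks, scale = scale,
                       clip_negative = clip_negative),
         train_dates = panel$week_ending_date,
         observed = panel),
    class = "wemc_forecaster"
  )
}

fourier_design <- function(t_idx, fourier_order, period_weeks) {
  cols <- list(`(Intercept)` = rep(1, length(t_idx)), trend = t_idx)
  for (j in seq_len(fourier_order)) {
    cols[[paste0("sin", j)]] <- sin(2 * pi * j * t_idx / period_weeks)
    cols[[paste0("cos", j)]] <- cos(2 * pi * j * t_idx / period_weeks)
  }
  do.call(cbind, cols)
}

forecaster_values <- function(model, t_idx) {
  X <- fourier_design(t_idx, model$config$fourier_order,
                      model$config$period_weeks)
  yhat <- X %*% model$coefficients
  if (model$config$scale == "log1p") {
    yhat <- expm1(yhat)
    yhat[yhat < 0] <- 0
  } else if (model$config$clip_negative) {
    yhat[yhat < 0] <- 0
  }
  yhat
}

#' Forecast a fitted harmonic model
#'
#' Extends the fitted trend + harmonics `horizon` weeks past the training
#' range, at 7-day spacing starting 7 days after the last training week.
#' Forecasts are real-valued (not rounded to integers): downstream
#' exceedance indicators compare consecutive values with a strict
#' inequality, and rounding would create spurious ties.
#'
#' @param model A `wemc_forecaster`.
#' @param horizon Weeks to forecast (default: the fitted config's).
#' @return A `mortality_panel` of `horizon` rows.
#' @export
forecast_panel <- function(model, horizon = NULL) {
  stopifnot(inherits(model, "wemc_forecaster"))
  horizon <- horizon %||% model$config$horizon
  if (horizon < 1) abort("horizon must be >= 1")
  n_train <- length(model$train_dates)
  t_idx <- n_train - 1 + seq_len(horizon)
  yhat <- forecaster_values(model, t_idx)
  out <- tibble::tibble(
    week_ending_date = tail(model$train_dates, 1) + 7 * seq_len(horizon)
  )
  out[colnames(yhat)] <- as.data.frame(yhat)
  as_mortality_panel(out)
}

#' In-sample observed-vs-fitted correlations
#'
#' Pearson correlation between each cause's observed counts and the
#' model's in-sample fitted values, the usual goodness-of-fit summary for
#' the seasonal forecaster. A zero-variance observed series has no
#' defined correlation and is reported as `NA` with a warning.
#'
#' @param panel The training `mortality_panel`.
#' @param model A `wemc_forecaster` fitted to `panel`'s date range.
#' @return A tibble with columns `cause`, `correlation`.
#' @export
fitted_correlations <- function(panel, model) {
  stopifnot(inherits(model, "wemc_forecaster"))
  validate_panel(panel)
  if (!identical(panel$week_ending_date, model$train_dates)) {
    abort("panel dates do not match the model's training range")
  }
  yhat <- forecaster_values(model, seq_len(nrow(panel)) - 1)
  obs <- panel_counts(panel)
  r <- vapply(seq_len(ncol(obs)), function(j) {
    if (stats::sd(obs[, j]) == 0) {
      warn(paste0("zero-variance observed series for `",
                  colnames(obs)[j], "`; correlation undefined"))
      return(NA_real_)
    }
    cor(obs[, j], yhat[, j])
  }, numeric(1))
  tibble::tibble(cause = colnames(obs), correlation = r)
}

#' @export
print.wemc_forecaster <- function(x, ...) {
  cat("<wemc_forecaster> ", ncol(x$coefficients), " causes, ",
      length(x$train_dates), " training weeks, fourier_order ",
      x$config$fourier_order, ", scale ", x$config$scale, "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_forecaster One row per cause and coefficient.
#' @param x,object A `wemc_forecaster`.
#' @param ... Unused.
#' @export
tidy.wemc_forecaster <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    cause = rep(colnames(co), each = nrow(co)),
    term = rep(rownames(co), times = ncol(co)),
    estimate = as.vector(co)
  )
}

#' @describeIn fit_forecaster One row per cause with the in-sample
#'   correlation and training size.
#' @export
glance.wemc_forecaster <- function(x, ...) {
  r <- fitted_correlations(x$observed, x)
  tibble::tibble(cause = r$cause, r_fitted = r$correlation,
                 n_weeks = length(x$train_dates),
                 fourier_order = x$config$fourier_order)
}

#' Plot observed counts with fitted values and a forecast
#'
#' @param object A `wemc_forecaster`.
#' @param horizon Forecast weeks to draw (default from the fit config).
#' @param ... Unused.
#' @return A ggplot object faceted by cause.
#' @export
autoplot.wemc_forecaster <- function(object, horizon = NULL, ...) {
  obs <- object$observed
  fitted <- forecaster_values(object, seq_len(nrow(obs)) - 1)
  fc <- forecast_panel(object, horizon)
  long_obs <- tidyr::pivot_longer(obs, dplyr::all_of(cause_labels(obs)),
                                  names_to = "cause", values_to = "count")
  fit_df <- tibble::tibble(
    week_ending_date = rep(obs$week_ending_date, ncol(fitted)),
    cause = rep(colnames(fitted), each = nrow(fitted)),
    count = as.vector(fitted), what = "fitted"
  )
  fc_df <- tidyr::pivot_longer(fc, dplyr::all_of(cause_labels(fc)),
                               names_to = "cause", values_to = "count")
  fc_df$what <- "forecast"
  ggplot2::ggplot(long_obs,
                  ggplot2::aes(.data$week_ending_date, .data$count)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = dplyr::bind_rows(fit_df, fc_df),
                       ggplot2::aes(colour = .data$what)) +
    ggplot2::facet_wrap(~cause, scales = "free_y") +
    ggplot2::labs(x = "week ending", y = "weekly deaths", colour = NULL)
}
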