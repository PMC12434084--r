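#' Per-window WCMI estimates
#'
#' Splits the exceedance matrix by segment tag and estimates the
#' exceedance probability separately on the observed and forecast
#' windows. The single pair straddling the observed/forecast boundary is
#' excluded from both windows by default; `boundary` can assign it to
#' either window instead.
#'
#' @param matrix An `exceedance_matrix` with segment tags.
#' @param boundary `"drop"`, `"observed"`, or `"forecast"`.
#' @return A tibble: `cause`, `n_observed`, `p_hat_observed`,
#'   `n_forecast`, `p_hat_forecast`, `abs_diff`.
#' @export
windowed_estimates <- function(matrix,
                               boundary = c("drop", "observed", "forecast")) {
  stopifnot(inherits(matrix, "exceedance_matrix"))
  boundary <- match.arg(boundary)
  seg <- matrix$segment
  if (boundary != "drop") seg[seg == "boundary"] <- boundary
  ind <- exceedance_indicators(matrix)
  one_window <- function(which) {
    rows <- seg == which
    if (!any(rows)) abort(paste0("empty ", which, " window"))
    list(n = sum(rows), p = colMeans(ind[rows, , drop = FALSE]))
  }
  obs <- one_window("observed")
  fc <- one_window("forecast")
  tibble::tibble(
    cause = colnames(ind),
    n_observed = obs$n, p_hat_observed = unname(obs$p),
    n_forecast = fc$n, p_hat_forecast = unname(fc$p),
    abs_diff = unname(abs(obs$p - fc$p))
  )
}

#' Euclidean distance between probability vectors
#'
#' @param x,y Equal-length numeric vectors.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch")
  sqrt(sum((x - y)^2))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' The Mann-Whitney statistic of the first sample — the number of pairs
#' (x_i, y_j) with x_i > y_j, ties counted as 1/2 — with a two-sided
#' p-value from the normal approximation with continuity correction and
#' tie-corrected variance (no exact-distribution branch, whatever the
#' sample size).
#'
#' @param x,y Non-empty numeric samples.
#' @return A tibble with columns `W`, `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Validate forecast-window exceedance estimates
#'
#' Compares the exceedance probabilities estimated on the observed
#' window against those from the forecast window: the per-cause
#' difference table, the Euclidean distance between the two probability
#' vectors, and a two-sided Wilcoxon rank-sum test of the two columns at
#' the 5% level. When the training panel and fitted forecaster are
#' supplied, per-cause observed-vs-fitted correlations are appended.
#'
#' @param matrix An `exceedance_matrix` from a combined panel.
#' @param panel,model Optional training panel and `wemc_forecaster` for
#'   [fitted_correlations()].
#' @param boundary Boundary-pair handling, see [windowed_estimates()].
#' @param alpha Significance level for the verdict string.
#' @return A `wemc_validation` object; see [tidy()] / [glance()].
#' @export
validate_forecast <- function(matrix, panel = NULL, model = NULL,
                              boundary = c("drop", "observed", "forecast"),
                              alpha = 0.05) {
  boundary <- match.arg(boundary)
  est <- windowed_estimates(matrix, boundary = boundary)
  dist <- euclidean_distance(est$p_hat_observed, est$p_hat_forecast)
  wt <- wilcoxon_rank_sum(est$p_hat_observed, est$p_hat_forecast)
  corr <- if (!is.null(panel) && !is.null(model)) {
    fitted_correlations(panel, model)
  }
  verdict <- if (wt$p_value > alpha) {
    paste0("no significant difference between observed and forecast",
           " exceedance probabilities (p = ", signif(wt$p_value, 2),
           " > ", alpha, ")")
  } else {
    paste0("observed and forecast exceedance probabilities differ",
           " significantly (p = ", signif(wt$p_value, 2), " <= ", alpha, ")")
  }
  structure(
    list(estimates = est, euclidean_distance = dist,
         wilcoxon_W = wt$W, wilcoxon_p = wt$p_value,
         correlations = corr, boundary = boundary, alpha = alpha,
         verdict = verdict),
    class = "wemc_validation"
  )
}

#' @export
print.wemc_validation <- function(x, ...) {
  cat("Forecast validation (", nrow(x$estimates), " causes; boundary pair ",
      if (x$boundary == "drop") "dropped" else paste0("-> ", x$boundary),
      ")\n", sep = "")
  cat("  Euclidean distance: ", format(round(x$euclidean_distance, 4)), "\n",
      "  Wilcoxon rank-sum:  W = ", format(x$wilcoxon_W),
      ", p = ", format(round(x$wilcoxon_p, 4)), "\n",
      "  ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' @describeIn validate_forecast Per-cause observed/forecast estimates
#'   (and correlations when available).
#' @param x,object A `wemc_validation`.
#' @param ... Unused.
#' @export
tidy.wemc_validation <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$correlations)) {
    out <- dplyr::left_join(out, x$correlations, by = "cause")
  }
  out
}

#' @describeIn validate_forecast One-row summary statistics.
#' @export
glance.wemc_validation <- function(x, ...) {
  tibble::tibble(euclidean_distance = x$euclidean_distance,
                 wilcoxon_W = x$wilcoxon_W, wilcoxon_p = x$wilcoxon_p,
                 n_causes = nrow(x$estimates))
}

#' @describeIn validate_forecast Observed-vs-forecast estimate scatter
#'   around the identity line.
#' @export
autoplot.wemc_validation <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(.data$p_hat_observed, .data$p_hat_forecast,
                               label = .data$cause)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "observed-window p-hat", y = "forecast-window p-hat")
}
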