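#' Build the weekly exceedance indicator matrix
#'
#' Phase II. For each cause and each consecutive week pair (t, t + 1) the
#' weekly exceedance in mortality count (WEMC) indicator is 1 when the
#' later week's count strictly exceeds the earlier week's, and 0
#' otherwise (ties count as no exceedance). A T-week panel yields exactly
#' T - 1 indicator rows; each row is dated by the later week of its pair.
#'
#' When the panel carries a `segment` column (from [combine_panels()]),
#' each indicator row is tagged `"observed"` (both weeks observed),
#' `"forecast"` (both forecast), or `"boundary"` (the single pair that
#' straddles the last observed and first forecast week), so windowed
#' estimates can include or exclude the straddling pair explicitly.
#'
#' @param panel A `mortality_panel` with at least 2 weeks.
#' @return A tibble of class `exceedance_matrix`: `pair_date`, `segment`,
#'   then one 0/1 column per cause.
#' @examples
#' df <- tibble::tibble(
#'   week_ending_date = as.Date("2020-01-04") + 7 * (0:3),
#'   DIAMEL = c(5, 7, 7, 6)
#' )
#' build_exceedance(as_mortality_panel(df)) # indicators 1, 0, 0
#' @export
build_exceedance <- function(panel) {
  validate_panel(panel)
  t_n <- nrow(panel)
  if (t_n < 2) abort("need at least 2 weeks to form an exceedance pair")
  counts <- panel_counts(panel)
  ind <- (counts[-1, , drop = FALSE] > counts[-t_n, , drop = FALSE]) * 1L
  if ("segment" %in% names(panel)) {
    earlier <- panel$segment[-t_n]
    later <- panel$segment[-1]
    seg <- ifelse(earlier == later, later, "boundary")
  } else {
    seg <- rep("observed", t_n - 1)
  }
  out <- tibble::tibble(pair_date = panel$week_ending_date[-1], segment = seg)
  out[colnames(ind)] <- as.data.frame(ind)
  class(out) <- c("exceedance_matrix", class(tibble::tibble()))
  out
}

exceedance_indicators <- function(matrix) {
  as.matrix(matrix[cause_labels(matrix)])
}

#' Estimate WCMI binomial parameters
#'
#' The weekly change in mortality indicator (WCMI) for cause i is the
#' number of week pairs at which exceedance occurs, modelled as
#' binomial(n, p_i) with n the number of indicator rows. The estimate
#' `p_hat` is the per-cause proportion of 1s, kept at full precision;
#' `round_digits = 3` reproduces the conventional 3-decimal display.
#'
#' @param matrix An `exceedance_matrix`.
#' @param round_digits Optional digits for display rounding of `p_hat`.
#' @return A tibble with columns `cause`, `n`, `ones`, `p_hat`.
#' @export
estimate_wcmi <- function(matrix, round_digits = NULL) {
  stopifnot(inherits(matrix, "exceedance_matrix"))
  if (nrow(matrix) == 0) abort("empty exceedance matrix")
  ind <- exceedance_indicators(matrix)
  est <- tibble::tibble(
    cause = colnames(ind),
    n = nrow(ind),
    ones = as.integer(unname(colSums(ind))),
    p_hat = unname(colSums(ind)) / nrow(ind)
  )
  if (!is.null(round_digits)) est$p_hat <- round(est$p_hat, round_digits)
  est
}

#' Chi-square test of independence between cause and exceedance
#'
#' Arranges the per-cause exceed / non-exceed counts as a K x 2
#' contingency table and applies Pearson's chi-square test without
#' continuity correction (df = K - 1), with Cramer's V
#' `sqrt(chi2 / (N * min(K - 1, 1)))`, N = K * n, as the effect size. A
#' small V supports treating the per-cause indicators as independent,
#' which the joint-probability machinery assumes.
#'
#' @param matrix An `exceedance_matrix`.
#' @return A `wemc_independence` object; see [tidy()] / [glance()].
#' @export
independence_test <- function(matrix) {
  est <- estimate_wcmi(matrix)
  tab <- cbind(exceed = est$ones, no_exceed = est$n - est$ones)
  rownames(tab) <- est$cause
  if (any(colSums(tab) == 0)) {
    abort("degenerate contingency table: a margin is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n_total <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (n_total * min(nrow(tab) - 1, 1)))
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, cramers_v = v, table = tab),
    class = "wemc_independence"
  )
}

#' @export
print.wemc_independence <- function(x, ...) {
  cat("Chi-square test of independence (cause x exceedance)\n",
      "X-squared = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format(x$p_value), "\n",
      "Cramer's V = ", format(x$cramers_v), "\n", sep = "")
  invisible(x)
}

#' @describeIn independence_test The contingency table, one row per cause.
#' @param x,object A `wemc_independence`.
#' @param ... Unused.
#' @export
tidy.wemc_independence <- function(x, ...) {
  tibble::tibble(cause = rownames(x$table),
                 exceed = unname(x$table[, "exceed"]),
                 no_exceed = unname(x$table[, "no_exceed"]))
}

#' @describeIn independence_test One-row summary of the test.
#' @export
glance.wemc_independence <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p_value = x$p_value, cramers_v = x$cramers_v)
}

#' Plot an exceedance matrix as a binary heatmap
#'
#' @param object An `exceedance_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot, weeks on the x axis, causes on the y axis.
#' @export
autoplot.exceedance_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(cause_labels(object)),
                              names_to = "cause", values_to = "indicator")
  ggplot2::ggplot(long, ggplot2::aes(.data$pair_date, .data$cause,
                                     fill = factor(.data$indicator))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "grey20"),
                               name = "exceedance") +
    ggplot2::labs(x = "week ending (later week of pair)", y = NULL)
}

#' Read or write an exceedance matrix as CSV
#'
#' Layout: `pair_date,segment,<cause1>,...` with 0/1 indicator columns.
#'
#' @param matrix An `exceedance_matrix`.
#' @param destination,source File path.
#' @return The matrix (invisibly for write).
#' @export
write_exceedance <- function(matrix, destination) {
  stopifnot(inherits(matrix, "exceedance_matrix"))
  readr::write_csv(matrix, destination, progress = FALSE)
  invisible(matrix)
}

#' @rdname write_exceedance
#' @export
read_exceedance <- function(source) {
  x <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pair_date", "segment") %in% names(x))) {
    abort("expected columns `pair_date` and `segment`")
  }
  ind <- as.matrix(x[setdiff(names(x), c("pair_date", "segment"))])
  if (!all(ind %in% c(0, 1))) abort("indicator entries must be 0 or 1")
  class(x) <- c("exceedance_matrix", class(tibble::tibble()))
  x
}
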