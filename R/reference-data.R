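#' Published reference WCMI estimates
#'
#' Per-cause weekly exceedance probability estimates from the published
#' analysis of the CDC "Weekly Provisional Counts of Deaths" table (14
#' causes of death, combined observed + forecast window of 298 weeks,
#' n = 297 week pairs). Shipped so probability queries and worked
#' examples can run without the CDC extract.
#'
#' @return A tibble with columns `cause` (C1..C14), `label` (the COD
#'   abbreviation, e.g. DIAMEL for diabetes mellitus), `n`, `p_hat`.
#' @examples
#' est <- reference_estimates()
#' query_probabilities(est, "C1=141")
#' @export
reference_estimates <- function() {
  readr::read_csv(
    system.file("extdata", "wcmi_reference_estimates.csv", package = "wemc"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published observed- vs forecast-window estimates
#'
#' The per-cause exceedance probabilities estimated separately on the
#' 194-week observed window and the 104-week forecast window of the
#' published CDC analysis; the inputs to its validation statistics
#' (Euclidean distance, Wilcoxon rank-sum).
#'
#' @return A tibble with columns `cause`, `p_hat_observed`,
#'   `p_hat_forecast`.
#' @export
reference_window_estimates <- function() {
  readr::read_csv(
    system.file("extdata", "window_reference_estimates.csv", package = "wemc"),
    show_col_types = FALSE, progress = FALSE
  )
}
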