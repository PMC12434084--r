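#' Weekly mortality panels
#'
#' A mortality panel is a tibble with one row per week-ending date and one
#' numeric column per cause of death, plus an optional `segment` column
#' (`"observed"` or `"forecast"`). Dates must be strictly increasing at an
#' exact 7-day spacing, and counts must be nonnegative (integers for
#' observed or simulated data; forecasts may be real-valued).
#'
#' @param x A data frame with a `week_ending_date` column (`Date`), one
#'   numeric column per cause, and optionally a `segment` column.
#' @return A tibble of class `mortality_panel`.
#' @examples
#' df <- tibble::tibble(
#'   week_ending_date = as.Date("2020-01-04") + 7 * (0:3),
#'   DIAMEL = c(5, 7, 7, 6)
#' )
#' as_mortality_panel(df)
#' @export
as_mortality_panel <- function(x) {
  x <- tibble::as_tibble(x)
  validate_panel(x)
  class(x) <- c("mortality_panel", class(tibble::tibble()))
  x
}

#' Cause labels of a panel or exceedance matrix
#'
#' @param x A `mortality_panel` or `exceedance_matrix`.
#' @return Character vector of cause column names.
#' @export
cause_labels <- function(x) {
  setdiff(names(x), c("week_ending_date", "pair_date", "segment"))
}

panel_counts <- function(x) {
  as.matrix(x[cause_labels(x)])
}

validate_panel <- function(x) {
  if (!"week_ending_date" %in% names(x)) {
    abort("panel must have a `week_ending_date` column")
  }
  d <- x$week_ending_date
  if (!inherits(d, "Date")) abort("`week_ending_date` must be a Date column")
  causes <- cause_labels(x)
  if (length(causes) == 0) abort("panel has no cause columns")
  if (anyDuplicated(causes)) abort("duplicated cause labels")
  if (nrow(x) >= 2) {
    dd <- as.numeric(diff(d))
    if (any(dd <= 0)) {
      abort(paste0("dates not strictly increasing at row ",
                   which(dd <= 0)[1] + 1))
    }
    if (any(dd != 7)) {
      abort(paste0("weeks not at exact 7-day spacing at row ",
                   which(dd != 7)[1] + 1,
                   " (missing or extra weeks)"))
    }
  }
  for (cl in causes) {
    v <- x[[cl]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in column `", cl, "`"))
    if (anyNA(v)) {
      abort(paste0("missing count in column `", cl, "` at row ",
                   which(is.na(v))[1]))
    }
    if (any(v < 0)) {
      abort(paste0("negative count in column `", cl, "` at row ",
                   which(v < 0)[1]))
    }
  }
  if ("segment" %in% names(x)) {
    bad <- !x$segment %in% c("observed", "forecast")
    if (any(bad)) abort("`segment` entries must be \"observed\" or \"forecast\"")
  }
  invisible(x)
}

#' Read or write a mortality panel as CSV
#'
#' The CSV layout is the wide CDC layout: a `week_ending_date` column
#' (ISO-8601 dates) followed by one column per cause. An optional
#' `column_map` renames verbatim source headers (e.g. the CDC's
#' `"Diabetes mellitus (E10-E14)"`) to short cause labels on read.
#'
#' @param source Path to a CSV file.
#' @param column_map Optional named character vector, `c(new = "old header")`.
#' @return A `mortality_panel`.
#' @export
read_panel <- function(source, column_map = NULL) {
  x <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    nm <- names(x)
    for (i in seq_along(column_map)) {
      nm[nm == column_map[[i]]] <- names(column_map)[i]
    }
    names(x) <- nm
  }
  if ("week_ending_date" %in% names(x) && !inherits(x$week_ending_date, "Date")) {
    x$week_ending_date <- as.Date(x$week_ending_date)
  }
  if (anyDuplicated(x$week_ending_date)) {
    abort(paste0("duplicated date at row ",
                 which(duplicated(x$week_ending_date))[1]))
  }
  as_mortality_panel(x)
}

#' @rdname read_panel
#' @param panel A `mortality_panel`.
#' @param destination Path to write.
#' @return `write_panel` returns `panel` invisibly.
#' @export
write_panel <- function(panel, destination) {
  validate_panel(panel)
  readr::write_csv(panel, destination, progress = FALSE)
  invisible(panel)
}

#' Combine an observed panel with its forecast continuation
#'
#' The forecast must continue the observed panel at exactly 7 days after
#' its last week, with identical cause columns in identical order. Rows of
#' the result carry a `segment` tag (`"observed"` / `"forecast"`); a
#' 194-week observed panel plus a 104-week forecast yields the 298-week
#' combined panel whose 297 consecutive week pairs feed the exceedance
#' matrix.
#'
#' @param observed,forecast `mortality_panel` objects.
#' @return A `mortality_panel` with a `segment` column.
#' @export
combine_panels <- function(observed, forecast) {
  validate_panel(observed)
  validate_panel(forecast)
  if (!identical(cause_labels(observed), cause_labels(forecast))) {
    abort("cause labels differ between observed and forecast panels")
  }
  gap <- as.numeric(forecast$week_ending_date[1] -
                      tail(observed$week_ending_date, 1))
  if (gap != 7) {
    abort(paste0("forecast must start 7 days after the last observed week",
                 " (gap is ", gap, " days)"))
  }
  observed$segment <- "observed"
  forecast$segment <- "forecast"
  out <- dplyr::bind_rows(observed, forecast)
  out <- dplyr::relocate(out, "segment", .after = "week_ending_date")
  as_mortality_panel(out)
}

#' @export
print.mortality_panel <- function(x, ...) {
  cat("<mortality_panel> ", nrow(x), " weeks x ", length(cause_labels(x)),
      " causes (", format(x$week_ending_date[1]), " to ",
      format(tail(x$week_ending_date, 1)), ")\n", sep = "")
  NextMethod()
}

#' Plot weekly counts per cause
#'
#' @param object A `mortality_panel`.
#' @param ... Unused.
#' @return A ggplot object, one facet per cause; forecast segments are
#'   drawn dashed when a `segment` column is present.
#' @export
autoplot.mortality_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(cause_labels(object)),
                              names_to = "cause", values_to = "count")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$week_ending_date, .data$count))
  if ("segment" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(linetype = .data$segment))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~cause, scales = "free_y") +
    ggplot2::labs(x = "week ending", y = "weekly deaths")
}
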