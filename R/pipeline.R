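#' Configure an end-to-end pipeline run
#'
#' Bundles everything [run_pipeline()] needs: exactly one input source (a
#' wide weekly-counts CSV or a [simulation_config()]), the forecaster
#' settings, boundary handling for windowed estimates, optional
#' probability and sum-distribution queries, and the seed. Defaults
#' mirror the reference CDC analysis: a 104-week horizon, so a 194-week
#' observed panel yields a 298-week combined panel and n = 297 indicator
#' pairs; marginal rounding off.
#'
#' @param input_csv Path to a wide weekly-counts CSV, or `NULL`.
#' @param simulation A `simulation_config`, or `NULL` (exactly one of
#'   the two must be given).
#' @param horizon,fourier_order,scale Forecaster settings, see
#'   [fit_forecaster()].
#' @param boundary Boundary-pair handling, see [windowed_estimates()].
#' @param probability_queries Character vector in the [parse_query()]
#'   grammar (comma-joined clauses are joint events).
#' @param sum_queries Character vector like `"50:0.5x5 T<=120"`:
#'   components in [binomial_components()] syntax, a space, then an
#'   event on `T`.
#' @param rounding Marginal rounding for joint queries.
#' @param column_map Optional header renaming for `input_csv`.
#' @param seed Integer seed (only simulation consumes randomness).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL, simulation = NULL,
                            horizon = 104, fourier_order = 10,
                            scale = "identity",
                            boundary = "drop",
                            probability_queries = character(),
                            sum_queries = character(),
                            rounding = "none",
                            column_map = NULL,
                            seed = 1L) {
  if (is.null(input_csv) == is.null(simulation)) {
    abort("give exactly one of `input_csv` or `simulation`")
  }
  structure(
    list(input_csv = input_csv, simulation = simulation,
         horizon = as.integer(horizon),
         fourier_order = as.integer(fourier_order), scale = scale,
         boundary = boundary,
         probability_queries = probability_queries,
         sum_queries = sum_queries, rounding = rounding,
         column_map = column_map, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
          class = "wemc_stage_error", stage = name)
  })
}

parse_sum_query <- function(q) {
  parts <- strsplit(trimws(q), "\\s+")[[1]]
  if (length(parts) != 2) {
    abort(paste0("sum query must be `<components> <event>`: `", q, "`"))
  }
  comp <- binomial_components(parts[1])
  s <- gsub(" ", "", parts[2])
  m <- regmatches(s, regexec("^([0-9]+)(<=|<)T(<=|<)([0-9]+)$", s))[[1]]
  if (length(m)) {
    lo <- as.numeric(m[2]) + if (m[3] == "<") 1 else 0
    hi <- as.numeric(m[5]) - if (m[4] == "<") 1 else 0
    return(list(components = comp, event = wemc_event("between", lo, hi)))
  }
  m <- regmatches(s, regexec("^T(=|<=|>=|<|>)([0-9]+)$", s))[[1]]
  if (!length(m)) abort(paste0("cannot parse sum event `", parts[2], "`"))
  kind <- c(`=` = "eq", `<=` = "le", `>=` = "ge", `<` = "lt", `>` = "gt")[[m[2]]]
  list(components = comp, event = wemc_event(kind, as.numeric(m[3])))
}

#' Run the three-phase exceedance pipeline
#'
#' Executes load/simulate -> fit -> forecast -> combine -> exceedance
#' matrix -> WCMI estimation -> independence test -> probability and
#' sum-distribution queries -> forecast validation. With an
#' `output_dir`, every artifact is written (CSV/JSON) together with a
#' manifest recording the config hash, seed, and per-file checksums;
#' rerunning an identical config reproduces identical artifacts. Any
#' stage failure aborts with a `wemc_stage_error` carrying the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for artifacts.
#' @return A `wemc_pipeline_report` list with elements `panel`
#'   (combined), `model`, `exceedance`, `estimates`, `independence`,
#'   `probabilities`, `sum_probabilities`, `validation`, `manifest`.
#' @examples
#' cfg <- pipeline_config(
#'   simulation = simulation_config(194, c("A", "B"), baseline = c(400, 900),
#'                                  yearly_amplitude = 0.1, seed = 11),
#'   probability_queries = "A>=100"
#' )
#' rep <- run_pipeline(cfg)
#' rep$estimates
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  observed <- stage("load", {
    if (!is.null(config$input_csv)) {
      read_panel(config$input_csv, column_map = config$column_map)
    } else {
      simulate_panel(config$simulation)
    }
  })
  model <- stage("fit", fit_forecaster(
    observed, horizon = config$horizon,
    fourier_order = config$fourier_order, scale = config$scale
  ))
  fc <- stage("forecast", forecast_panel(model))
  combined <- stage("combine", combine_panels(observed, fc))
  em <- stage("exceedance", build_exceedance(combined))
  est <- stage("estimate", estimate_wcmi(em))
  indep <- stage("independence", independence_test(em))
  probs <- stage("probability", {
    if (length(config$probability_queries)) {
      query_probabilities(est, config$probability_queries,
                          rounding = config$rounding)
    } else {
      tibble::tibble(query = character(), probability = numeric())
    }
  })
  sums <- stage("sum_distribution", {
    if (length(config$sum_queries)) {
      tibble::tibble(
        query = config$sum_queries,
        probability = vapply(config$sum_queries, function(q) {
          pq <- parse_sum_query(q)
          sum_event_probability(pq$components, pq$event)
        }, numeric(1), USE.NAMES = FALSE)
      )
    } else {
      tibble::tibble(query = character(), probability = numeric())
    }
  })
  val <- stage("validation", validate_forecast(
    em, panel = observed, model = model, boundary = config$boundary
  ))
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed,
                   n_weeks_observed = nrow(observed),
                   n_weeks_combined = nrow(combined),
                   n_pairs = nrow(em))
  report <- structure(
    list(panel = combined, model = model, exceedance = em, estimates = est,
         independence = indep, probabilities = probs,
         sum_probabilities = sums, validation = val, manifest = manifest),
    class = "wemc_pipeline_report"
  )
  if (!is.null(output_dir)) {
    stage("write", write_pipeline_report(report, output_dir))
  }
  report
}

write_pipeline_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)
  write_panel(report$panel, path("combined_panel.csv"))
  write_exceedance(report$exceedance, path("exceedance_matrix.csv"))
  readr::write_csv(report$estimates, path("wcmi_estimates.csv"),
                   progress = FALSE)
  jsonlite::write_json(glance(report$independence), path("independence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(report$probabilities, path("probabilities.csv"),
                   progress = FALSE)
  readr::write_csv(report$sum_probabilities, path("sum_probabilities.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(report$validation), path("validation_table.csv"),
                   progress = FALSE)
  jsonlite::write_json(glance(report$validation), path("validation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c("combined_panel.csv", "exceedance_matrix.csv",
             "wcmi_estimates.csv", "independence.json", "probabilities.csv",
             "sum_probabilities.csv", "validation_table.csv",
             "validation.json")
  manifest <- c(report$manifest,
                list(files = as.list(tools::md5sum(vapply(files, path,
                                                          character(1))))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.wemc_pipeline_report <- function(x, ...) {
  cat("<wemc_pipeline_report>\n")
  cat("  combined panel: ", nrow(x$panel), " weeks x ",
      length(cause_labels(x$panel)), " causes; ", nrow(x$exceedance),
      " indicator pairs\n", sep = "")
  cat("  independence: p = ", format(round(x$independence$p_value, 3)),
      ", Cramer's V = ", format(round(x$independence$cramers_v, 3)), "\n",
      sep = "")
  cat("  validation: distance = ",
      format(round(x$validation$euclidean_distance, 3)),
      ", Wilcoxon p = ", format(round(x$validation$wilcoxon_p, 3)), "\n",
      sep = "")
  invisible(x)
}
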