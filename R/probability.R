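#' Specify a WCMI event
#'
#' An event on a binomial indicator count: equality, one-sided
#' inequalities (strict and non-strict kept distinct), or an inclusive
#' two-sided interval.
#'
#' @param kind One of `"eq"`, `"le"`, `"lt"`, `"ge"`, `"gt"`, `"between"`.
#' @param lower Integer bound (the only bound for all kinds but
#'   `"between"`).
#' @param upper Upper bound, `"between"` only (inclusive both ends).
#' @return A `wemc_event`.
#' @examples
#' wemc_event("eq", 141)
#' wemc_event("between", 138, 158)
#' @export
wemc_event <- function(kind = c("eq", "le", "lt", "ge", "gt", "between"),
                       lower, upper = NULL) {
  kind <- match.arg(kind)
  if (kind == "between") {
    if (is.null(upper)) abort("`between` needs both bounds")
    if (lower > upper) abort("`between` with lower > upper")
  } else if (!is.null(upper)) {
    abort("`upper` is only for `between` events")
  }
  structure(list(kind = kind, lower = as.numeric(lower),
                 upper = if (is.null(upper)) NULL else as.numeric(upper)),
            class = "wemc_event")
}

#' @export
format.wemc_event <- function(x, ...) {
  op <- c(eq = "=", le = "<=", lt = "<", ge = ">=", gt = ">")
  if (x$kind == "between") {
    paste0(x$lower, " <= T <= ", x$upper)
  } else {
    paste0("T ", op[[x$kind]], " ", x$lower)
  }
}

#' @export
print.wemc_event <- function(x, ...) {
  cat("<wemc_event> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Exact binomial probability of a WCMI event
#'
#' Each cause's WCMI is binomial(n, p); this evaluates P(event) by
#' summing the exact pmf (via the binomial cdf, switching to log-space
#' compensated summation for intervals so deep in a tail that cdf
#' differencing loses all precision). Bounds outside the 0..n support
#' clamp to the logically forced value (0 or 1 for tails, 0 for
#' eq/between fully outside).
#'
#' @param n Number of binomial trials (week pairs; 297 in the reference
#'   CDC analysis).
#' @param p Success probability in \[0, 1\].
#' @param event A [wemc_event()].
#' @return A probability in \[0, 1\].
#' @examples
#' event_probability(297, 0.475, wemc_event("eq", 141)) # 0.0463
#' @export
event_probability <- function(n, p, event) {
  stopifnot(inherits(event, "wemc_event"))
  if (n < 1 || n != round(n)) abort("n must be a positive integer")
  if (p < 0 || p > 1) abort("p must be in [0, 1]")
  a <- event$lower
  switch(event$kind,
    eq = {
      if (a < 0 || a > n || a != round(a)) 0 else dbinom(a, n, p)
    },
    le = {
      if (a < 0) 0 else if (a >= n) 1 else pbinom(floor(a), n, p)
    },
    lt = event_probability(n, p, wemc_event("le", ceiling(a) - 1)),
    ge = {
      if (a <= 0) 1 else if (a > n) 0
      else pbinom(ceiling(a) - 1, n, p, lower.tail = FALSE)
    },
    gt = event_probability(n, p, wemc_event("ge", floor(a) + 1)),
    between = {
      lo <- max(0, ceiling(a))
      hi <- min(n, floor(event$upper))
      if (lo > hi) return(0)
      val <- pbinom(hi, n, p) - pbinom(lo - 1, n, p)
      if (val < 1e-12) val <- exp(log_sum_exp(dbinom(lo:hi, n, p, log = TRUE)))
      min(max(val, 0), 1)
    }
  )
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Joint probability of independent WCMI events
#'
#' Under the validated independence of per-cause indicators, the joint
#' probability of events on several causes is the product of their
#' marginal probabilities. `rounding = "two_dp_marginals"` rounds each
#' marginal to 2 decimals before multiplying — the arithmetic used in
#' published illustrative tables — and exists purely for display
#' reproduction; the default multiplies full-precision marginals.
#'
#' @param events A list, each element a list with fields `n`, `p`, and
#'   `event` (a [wemc_event()]).
#' @param rounding `"none"` or `"two_dp_marginals"`.
#' @return A probability in \[0, 1\].
#' @examples
#' joint_probability(
#'   list(list(n = 297, p = 0.431, event = wemc_event("gt", 130)),
#'        list(n = 297, p = 0.498, event = wemc_event("gt", 130))),
#'   rounding = "two_dp_marginals"
#' ) # 0.38 * 0.98 = 0.3724
#' @export
joint_probability <- function(events, rounding = c("none", "two_dp_marginals")) {
  rounding <- match.arg(rounding)
  if (length(events) == 0) abort("empty event list")
  marg <- vapply(events, function(e) {
    event_probability(e$n, e$p, e$event)
  }, numeric(1))
  if (rounding == "two_dp_marginals") marg <- round(marg, 2)
  prod(marg)
}

#' Conditional probability between independent WCMI events
#'
#' Because the per-cause indicators are independent, any conditional
#' probability equals the target's marginal; the conditioning event's
#' probability is still computed to reject conditioning on a
#' zero-probability event.
#'
#' @param target,given Lists with fields `n`, `p`, `event`.
#' @return `event_probability(target$n, target$p, target$event)`.
#' @export
conditional_probability <- function(target, given) {
  p_given <- event_probability(given$n, given$p, given$event)
  if (p_given <= 0) {
    abort("conditioning event has probability 0; conditional undefined")
  }
  event_probability(target$n, target$p, target$event)
}

#' Parse a compact probability query
#'
#' Grammar: `<cause><op><int>` for one-sided events (`C1=141`,
#' `C2<136`, `C12>=203`) or `<int><=|<cause><=|<int>` for intervals
#' (`138<=C7<=158`, `138<C7<158`). Comma-joined clauses form a joint
#' event (`C6>130,C7>130`). Cause labels are resolved against a WCMI
#' estimates table ([estimate_wcmi()] output, columns `cause`, `n`,
#' `p_hat`).
#'
#' @param query Query string.
#' @param estimates Estimates tibble.
#' @return A list of `list(n, p, event)` clauses.
#' @export
parse_query <- function(query, estimates) {
  clauses <- trimws(strsplit(query, ",", fixed = TRUE)[[1]])
  if (length(clauses) == 0 || any(clauses == "")) {
    abort(paste0("empty clause in query `", query, "`"))
  }
  lapply(clauses, parse_clause, estimates = estimates)
}

parse_clause <- function(clause, estimates) {
  s <- gsub(" ", "", clause)
  lookup <- function(label) {
    i <- match(label, estimates$cause)
    if (is.na(i)) abort(paste0("unknown cause `", label, "`"))
    list(n = estimates$n[i], p = estimates$p_hat[i])
  }
  m <- regmatches(s, regexec(
    "^([0-9]+)(<=|<)([A-Za-z_][A-Za-z0-9_]*)(<=|<)([0-9]+)$", s))[[1]]
  if (length(m)) {
    sp <- lookup(m[4])
    lo <- as.numeric(m[2]) + if (m[3] == "<") 1 else 0
    hi <- as.numeric(m[6]) - if (m[5] == "<") 1 else 0
    return(c(sp, list(event = wemc_event("between", lo, hi), cause = m[4])))
  }
  m <- regmatches(s, regexec(
    "^([A-Za-z_][A-Za-z0-9_]*)(=|<=|>=|<|>)([0-9]+)$", s))[[1]]
  if (!length(m)) abort(paste0("cannot parse query clause `", clause, "`"))
  sp <- lookup(m[2])
  kind <- c(`=` = "eq", `<=` = "le", `>=` = "ge", `<` = "lt", `>` = "gt")[[m[3]]]
  c(sp, list(event = wemc_event(kind, as.numeric(m[4])), cause = m[2]))
}

#' Evaluate probability queries against WCMI estimates
#'
#' @param estimates A WCMI estimates tibble (`cause`, `n`, `p_hat`).
#' @param queries Character vector of queries in the [parse_query()]
#'   grammar; comma-joined clauses are joint events.
#' @param rounding Passed to [joint_probability()] for multi-clause
#'   queries.
#' @return A tibble with columns `query`, `probability`.
#' @examples
#' est <- tibble::tibble(cause = "C1", n = 297, p_hat = 0.475)
#' query_probabilities(est, c("C1=141", "C1>=141"))
#' @export
query_probabilities <- function(estimates, queries,
                                rounding = c("none", "two_dp_marginals")) {
  rounding <- match.arg(rounding)
  probs <- vapply(queries, function(q) {
    ev <- parse_query(q, estimates)
    if (length(ev) == 1) {
      event_probability(ev[[1]]$n, ev[[1]]$p, ev[[1]]$event)
    } else {
      joint_probability(ev, rounding = rounding)
    }
  }, numeric(1))
  tibble::tibble(query = queries, probability = unname(probs))
}
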