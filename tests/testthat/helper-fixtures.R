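# fixtures built in code: tiny panels and exceedance matrices

week0 <- as.Date("2020-01-04")

make_panel <- function(..., start = week0, segment = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  df <- tibble::tibble(week_ending_date = start + 7 * (0:(n - 1)))
  df[names(cols)] <- cols
  if (!is.null(segment)) df$segment <- segment
  as_mortality_panel(df)
}

# counts whose consecutive-pair indicators equal `ind` exactly
# (count rises by 1 on an exceedance week, stays flat otherwise: a tie,
# which the indicator definition maps to 0)
panel_from_indicators <- function(ind_matrix, segment = NULL) {
  ind_matrix <- as.matrix(ind_matrix)
  counts <- apply(ind_matrix, 2, function(v) cumsum(c(0, v)))
  df <- tibble::tibble(
    week_ending_date = week0 + 7 * (0:nrow(ind_matrix))
  )
  cn <- colnames(ind_matrix)
  if (is.null(cn)) cn <- paste0("C", seq_len(ncol(ind_matrix)))
  df[cn] <- as.data.frame(counts)
  if (!is.null(segment)) df$segment <- segment
  as_mortality_panel(df)
}

# exhaustive oracle: distribution of a sum of independent Bernoulli
# blocks, by enumerating all 2^(sum n) outcomes
enumerate_sum_pmf <- function(components) {
  probs <- rep(components$p, components$n)
  n_tot <- length(probs)
  stopifnot(n_tot <= 16)
  pmf <- numeric(n_tot + 1)
  for (code in 0:(2^n_tot - 1)) {
    bits <- as.integer(intToBits(code)[1:n_tot])
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    t <- sum(bits)
    pmf[t + 1] <- pmf[t + 1] + pr
  }
  pmf
}

# exhaustive two-sided permutation p-value for the rank-sum statistic
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  w_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  w_obs <- w_of(x, y)
  ws <- apply(idx, 2, function(i) w_of(pooled[i], pooled[-i]))
  mid <- length(x) * length(y) / 2
  mean(abs(ws - mid) >= abs(w_obs - mid) - 1e-12)
}
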