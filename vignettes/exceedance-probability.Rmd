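---
title: "Exceedance probabilities for weekly cause-specific mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exceedance probabilities for weekly cause-specific mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wemc)
```

## The model

`wemc` analyses a weekly panel of mortality counts $X_{it}$ (cause $i$,
week $t$) through a binary exceedance indicator

$$C_{it} = \begin{cases} 1 & X_{it} > X_{i,t-1} \\ 0 & X_{it} \le X_{i,t-1}, \end{cases}$$

so a tie is *not* an exceedance. Over $n$ consecutive week pairs the
per-cause exceedance count $\alpha_i = \sum_t C_{it}$ — the weekly change
in mortality indicator (WCMI) — is modelled as
$\alpha_i \sim \mathrm{bin}(n, p_i)$ with $\hat p_i$ the observed
proportion of 1s. Two assumptions underlie everything downstream:

* **Within-cause independence.** The indicator sequence of one cause is
  treated as i.i.d. Bernoulli. This is taken as given, not audited: for
  white noise around a level, consecutive-difference indicators are in
  fact weakly negatively autocorrelated, which makes binomial standard
  errors slightly conservative.
* **Across-cause independence of the $\alpha_i$.** Counts themselves can
  be strongly correlated across causes, but the *indicators* need not
  be. The package checks this with a chi-square test on the
  $K \times 2$ exceed/non-exceed table (no continuity correction,
  $\mathrm{df} = K - 1$) and Cramér's V
  $\sqrt{\chi^2 / (N \min(K-1, 1))}$, $N = Kn$. The joint and
  conditional probability functions then use the independence product.

Probabilities of single events are exact binomial sums; joint events are
products of marginals; conditionals collapse to marginals (the
conditioning event's probability is still computed, to refuse
conditioning on a null event).

The distribution of $T_N = \sum_{i=1}^N \alpha_i$ with *non-identical*
$(n_i, p_i)$ — a generalized Poisson-binomial — is computed two ways:

* **Exact:** iterated pairwise convolution of the component pmfs over the
  full index range (the convolution sum must start at index 0, otherwise
  the pmf would not normalise), accumulating in ascending support order.
  Direct convolution is used rather than FFT: every term stays
  nonnegative, so no round-off mass ever goes negative, and the support
  cap (default $\sum n_i \le 10^5$) keeps it fast.
* **Saddlepoint:** on the cumulant generating function
  $K(s) = \sum_i n_i \log(1 - p_i + p_i e^s)$, solve $K'(\hat s) = t$ by
  Newton iteration with a bisection safeguard (tolerance $10^{-10}$,
  at most 100 iterations; $K'$ is strictly increasing so a bracket always
  exists). The pmf uses the lattice saddlepoint density
  $e^{K(\hat s) - \hat s t} / \sqrt{2\pi K''(\hat s)}$; upper tails use
  the lattice Lugannani–Rice formula with continuity correction
  ($\tilde t = t - \tfrac12$, $u = 2\sinh(\hat s/2)\sqrt{K''(\hat s)}$),
  and lower tails are complements of upper tails.

## Phase I: the forecaster

Each cause is fitted independently by OLS on
$[1,\; t,\; \sin(2\pi j t/P),\; \cos(2\pi j t/P)]_{j=1..J}$ — a linear
trend plus Fourier yearly seasonality. Parameters:

| parameter | default | meaning |
|---|---|---|
| `horizon` | 104 weeks | forecast length; 104 weeks (2 years) matches the reference analysis |
| `fourier_order` ($J$) | 10 | yearly harmonic pairs; 10 is the convention of additive seasonal forecasters and resolves sub-monthly seasonal shape without chasing noise |
| `period_weeks` ($P$) | 365.25/7 ≈ 52.1775 | the yearly period in weeks |
| `scale` | identity | `log1p` fits on the log scale and back-transforms, guaranteeing nonnegative forecasts |

Design choices made deliberately:

* **No within-week ("weekly") seasonality.** The data are weekly
  aggregates, so a within-week cycle is unidentifiable; only yearly
  harmonics are fitted.
* **No changepoints, no uncertainty intervals.** Downstream machinery
  uses only point forecasts; dropping changepoints makes the fit a
  deterministic linear regression, reproducible to the bit.
* **Forecasts stay real-valued.** Rounding forecasts to integers would
  create spurious ties in the exceedance comparison (a tie maps to 0);
  with continuous forecasts, ties on the forecast segment have measure
  zero and the strict `>` of the indicator applies literally.

The fit requires at least $2(2 + 2J)$ weeks — twice the parameter count —
and refuses rank-deficient designs.

## Phase II: matrix construction and windows

A $T$-week combined panel yields exactly $T-1$ indicator rows (194
observed + 104 forecast weeks → 297 pairs). **Pair alignment:** each row
is attached to the *later* week of its pair. Whether one drops the first
or last endpoint week is presentational — either convention yields the
same $n = T - 1$ and identical counts — but the alignment determines the
segment tags: with 194 observed weeks there are 193 fully-observed pairs,
1 pair straddling the observed/forecast boundary, and 103 fully-forecast
pairs. The straddling pair is tagged `boundary` and excluded from both
windows by default in `windowed_estimates()`; it can be assigned to
either window explicitly, since reasonable readings of a "104-week
forecast window" give 103 or 104 indicator rows.

## Phase III: numerical choices

* **Deep-tail intervals.** $P(a \le \alpha \le b)$ is normally a cdf
  difference; when that difference falls below $10^{-12}$ (catastrophic
  cancellation territory) it is recomputed as a log-space sum of log-pmf
  terms combined with log-sum-exp.
* **Marginal rounding mode.** `rounding = "two_dp_marginals"` rounds each
  marginal to 2 decimals before multiplying. This exists solely to
  reproduce published joint-probability tables computed that way; it is a
  display artifact, not statistics, and the default multiplies
  full-precision marginals.
* **Strict vs non-strict events are distinct kinds.** `<` and `<=`
  (likewise `>` / `>=`) are never silently coerced; on an integer lattice
  they differ by one pmf atom.
* **Saddlepoint near the mean.** As $t$ approaches $K'(0)$ both $w$ and
  $u$ in the Lugannani–Rice formula go to 0 and $1/w - 1/u$ becomes a
  0/0 ratio. When $|\hat s|\sqrt{K''(\hat s)} < 10^{-4}$ the term is
  replaced by its analytic limit $K'''(\hat s) / (3 K''(\hat s)^{3/2})$,
  so integer-mean cases evaluate finitely with no blow-up.
* **Saddlepoint boundary points.** $t = 0$ and $t = \sum n_i$ have exact
  closed forms ($\prod (1-p_i)^{n_i}$, $\prod p_i^{n_i}$) and bypass the
  approximation; components with $p_i \in \{0, 1\}$ are refused (the
  caller should remove or shift the deterministic component).
* **Second-order density correction on by default.** The first-order
  lattice density drifts to roughly 8% relative error at the extreme
  support edges (where the exact pmf is near $10^{-300}$), while the
  $1 + (\lambda_4/8 - 5\lambda_3^2/24)$ correction keeps it under 1%
  everywhere we test; accuracy at negligible cost, so it is the default,
  with a flag to disable.
* **Validation statistics as published.** The rank-sum comparison of the
  observed- and forecast-window probability columns uses the *two-sample*
  Wilcoxon test even though the columns are paired by cause — the
  reference analysis did so, and the package reproduces the published
  procedure rather than silently "correcting" it to a signed-rank test.
  The statistic is the first-sample Mann–Whitney count with half-ties
  (this convention reproduces the published $W$), and the p-value always
  uses the normal approximation with continuity correction and
  tie-corrected variance, regardless of sample size; exact permutation
  enumeration exists only as a test oracle.

## The synthetic generator

Real CDC-style weekly mortality panels have a trend, strong yearly
seasonality, overdispersion relative to Poisson, and cross-cause count
correlations reaching ~0.9. The generator emulates exactly these
features: expected counts
$(b_k + \beta_k t)\bigl(1 + A_k \sin(2\pi (t - \phi_k)/52.1775)\bigr)$,
negative-binomial margins (size = `dispersion`; $\infty$ gives Poisson),
and a Gaussian copula on latent uniforms with a configurable PSD
correlation matrix. All randomness flows from the single config seed, and
the caller's RNG state is untouched.

What it deliberately does **not** emulate: reporting delays and backfill
of provisional counts, day-of-week structure, cause misclassification,
holiday effects, and pandemic-style level shifts. Passing tests on
synthetic panels therefore demonstrate the *machinery* — indicator
construction, estimation, probability computation — not that the binomial
model is adequate for any particular real surveillance series. The
copula correlation is attenuated on the count scale (discretisation and
unequal margins), so the achieved correlation is validated empirically
against a band rather than asserted exactly.

Where the generator needed values no reference prescribes, they were
fixed once at what a surveillance statistician would call realistic for
national weekly cause-specific counts: baselines from a few hundred to
tens of thousands of deaths per week, relative seasonal amplitude
~0.1–0.15 (winter-peaking), negative-binomial size ~50–200, and latent
cross-cause correlation 0.6 in the 14-cause demonstration configuration.

## Problem sizes used in tests

The suite checks the estimator's unbiasedness with 500 replicated
297-row indicator columns, chi-square null calibration with 1000
simulated 297×14 null matrices (Kolmogorov–Smirnov distance to uniform
< 0.05), Wilcoxon null rejection over 5000 replicates of 14-vs-14
samples (nominal 5%, observed must fall in 4–6%), exhaustive-enumeration
oracles up to $2^{12}$ outcomes, and saddlepoint-vs-exact grids with
$\sum n_i \le 1000$. These sizes give stable Monte-Carlo verdicts while
keeping the full suite fast on a single CPU.

## Known limitations

* The binomial WCMI model ignores the weak negative autocorrelation of
  consecutive-difference indicators and any autocorrelation induced by
  sustained surges.
* Joint probabilities assume independence of the $\alpha_i$; a
  copula-based dependent-joint model is out of scope.
* The forecaster is per-cause; cross-cause correlation is reported (and
  simulated) but not exploited for forecasting.
* The exact convolution is $O\!\bigl((\sum n_i)^2\bigr)$ in the worst
  case; beyond the cap only the saddlepoint route is available, and its
  accuracy is validated against the exact method on smaller grids, not
  proved.
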