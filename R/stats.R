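#' Spearman correlation with Fisher-z confidence interval
#'
#' The Spearman coefficient is the Pearson correlation of midranks
#' (average-rank ties). The p-value uses the t approximation with `n - 2`
#' degrees of freedom; the confidence interval applies the Fisher z transform
#' with standard error `1 / sqrt(n - 3)`. (The Fisher-z interval is one of
#' several conventions for rank correlations; intervals from other recipes
#' can differ in the second decimal, so treat the CI as descriptive.)
#'
#' @param a,b Numeric vectors of equal length `n >= 3`, neither constant.
#' @param alpha Two-sided miscoverage (default 0.05 for a 95% CI).
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `p_value`, `n`, `method`.
#' @export
spearman_with_ci <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 3L) abort("need at least 3 complete pairs.")
  if (safe_sd(a) == 0 || safe_sd(b) == 0) abort("constant input vector.")
  r <- stats::cor(rank(a), rank(b))
  p <- if (abs(r) >= 1) {
    2 / factorial(min(n, 10))  # degenerate perfect ordering; effectively 0 for large n
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se)
  tibble(r = r, ci_low = ci[1], ci_high = ci[2], p_value = min(p, 1), n = n,
         method = "spearman_fisher_z")
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums with average-rank ties. The p-value is exact
#' (full enumeration of the permutation distribution of the rank sum, which
#' is correct under ties as well) whenever the number of group assignments
#' `choose(n_a + n_b, n_a)` is small enough to enumerate; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. `exact` overrides the automatic choice.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact `NA` (auto), `TRUE` (force enumeration; errors if infeasible)
#'   or `FALSE` (force the normal approximation).
#' @return One-row tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NA) {
  if (length(a) == 0L || length(b) == 0L) abort("both samples must be non-empty.")
  res <- ranksum_test(c(a, b), c(rep(TRUE, length(a)), rep(FALSE, length(b))),
                      exact = exact)
  tibble(u = res$U, p_value = res$p, n_a = res$n_a, n_b = res$n_b,
         method = res$method)
}

#' Mean square deviation between two vectors
#'
#' `mean((a - b)^2)`: the squared-error companion to the Spearman correlation
#' when scoring predicted against measured fiber-type fractions.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mean_square_deviation <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) == 0L) abort("vectors must be non-empty.")
  mean((a - b)^2)
}

#' Compare estimated fractions between groups
#'
#' Per-group medians with seeded bootstrap confidence intervals and a
#' two-sided Mann-Whitney test between the first two groups.
#'
#' @param values Numeric vector of per-sample estimates.
#' @param groups Group label per sample (exactly two distinct groups for the
#'   test).
#' @param n_boot Bootstrap resamples for the median CI (default 2000).
#' @param alpha Two-sided miscoverage for the CI.
#' @param seed Integer seed for the bootstrap.
#' @return List with `summary` (tibble: group, n, median, ci_low, ci_high)
#'   and `test` (the [mann_whitney()] result).
#' @export
compare_groups <- function(values, groups, n_boot = 2000, alpha = 0.05,
                           seed = 1L) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2L) abort("compare_groups expects exactly two groups.")
  summary <- withr::with_seed(as.integer(seed), {
    dplyr::bind_rows(lapply(gl, function(g) {
      v <- values[groups == g]
      boots <- vapply(seq_len(n_boot), function(i) {
        stats::median(sample(v, replace = TRUE))
      }, numeric(1))
      tibble(
        group = g, n = length(v), median = stats::median(v),
        ci_low = stats::quantile(boots, alpha / 2, names = FALSE),
        ci_high = stats::quantile(boots, 1 - alpha / 2, names = FALSE)
      )
    }))
  })
  list(summary = summary,
       test = mann_whitney(values[groups == gl[1]], values[groups == gl[2]]))
}
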