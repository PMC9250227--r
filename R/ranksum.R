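## Shared Wilcoxon rank-sum / Mann-Whitney engine.
##
## Exact p-values come from full enumeration of the permutation distribution
## of the rank sum (midranks, so ties are handled exactly); this is feasible
## whenever choose(n, n_in) is small. Otherwise the normal approximation with
## tie correction and continuity correction is used.

RANKSUM_MAX_COMB <- 2e5

## values: pooled numeric vector; is_in: logical, TRUE for group a.
## exact: TRUE / FALSE / NA (auto by combination count).
ranksum_test <- function(values, is_in, exact = NA) {
  n_a <- sum(is_in)
  n_b <- sum(!is_in)
  if (n_a == 0L || n_b == 0L) abort("both groups must be non-empty.")
  N <- n_a + n_b
  r <- rank(values)
  W <- sum(r[is_in])
  U <- W - n_a * (n_a + 1) / 2
  n_comb <- choose(N, n_a)
  if (is.na(exact)) exact <- n_comb <= RANKSUM_MAX_COMB
  if (exact && n_comb > RANKSUM_MAX_COMB) {
    abort(sprintf("exact enumeration infeasible: choose(%d, %d) combinations.", N, n_a))
  }
  if (exact) {
    p <- ranksum_exact_p(r, n_a, W)
    method <- "exact_enumeration"
  } else {
    p <- ranksum_approx_p(r, n_a, n_b, U)
    method <- "normal_approximation"
  }
  list(W = W, U = U, p = p, n_a = n_a, n_b = n_b, method = method)
}

## two-sided exact p by enumerating every assignment of n_a of the midranks
ranksum_exact_p <- function(r, n_a, W_obs) {
  N <- length(r)
  cb <- utils::combn(N, n_a)
  Ws <- colSums(matrix(r[cb], nrow = n_a))
  mu <- n_a * (N + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

## normal approximation with tie correction and continuity correction,
## matching the classical large-sample Mann-Whitney test
ranksum_approx_p <- function(r, n_a, n_b, U) {
  N <- n_a + n_b
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- (n_a * n_b / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - n_a * n_b / 2
  z <- z - sign(z) * 0.5  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}
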