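# Independent oracles and small fixtures used across test files.

## deterministic toy UMI matrix with named genes
toy_counts <- function() {
  v <- matrix(
    c(9, 0, 2, 0,
      1, 5, 0, 3,
      0, 4, 6, 1,
      2, 1, 0, 7),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("MT-CO1", "ACTN2", "MYH7", "RPL5"),
                    paste0("n", 1:4))
  )
  count_matrix(v, "umi_counts")
}

## all K-part compositions of `total` (non-negative integers summing to total)
compositions <- function(total, K) {
  if (K == 1L) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(i) {
    cbind(i, compositions(total - i, K - 1L))
  }))
}

grid_objectives <- function(S, x, G) {
  E <- S %*% t(G)                      # genes x points
  colSums((E - x)^2)
}

## full simplex grid search at a single step
grid_search_simplex <- function(S, x, step) {
  K <- ncol(S)
  G <- compositions(round(1 / step), K) * step
  obj <- grid_objectives(S, x, G)
  i <- which.min(obj)
  list(fractions = G[i, ], objective = obj[i])
}

## multi-resolution simplex grid search with final step 0.001. The objective
## is convex, so refining around the best coarse cells finds the fine-grid
## minimizer; several candidate cells are kept per level for robustness.
grid_oracle <- function(S, x, steps = c(0.1, 0.02, 0.004, 0.001), top = 3L) {
  K <- ncol(S)
  G <- compositions(round(1 / steps[1]), K) * steps[1]
  obj <- grid_objectives(S, x, G)
  ord <- order(obj)[seq_len(min(top, length(obj)))]
  best <- G[ord, , drop = FALSE]
  for (lev in seq_along(steps)[-1]) {
    s <- steps[lev]
    prev <- steps[lev - 1]
    M <- round(1 / s)
    w <- ceiling(1.5 * prev / s)
    cand <- lapply(seq_len(nrow(best)), function(i) {
      b <- round(best[i, ] / s)
      rng <- lapply(seq_len(K - 1), function(k) {
        seq(max(0L, b[k] - w), min(M, b[k] + w))
      })
      g <- as.matrix(expand.grid(rng))
      last <- M - rowSums(g)
      ok <- last >= max(0L, b[K] - w) & last <= min(M, b[K] + w)
      cbind(g[ok, , drop = FALSE], last[ok])
    })
    G <- do.call(rbind, cand) * s
    obj <- grid_objectives(S, x, G)
    ord <- order(obj)[seq_len(min(top, length(obj)))]
    best <- G[ord, , drop = FALSE]
  }
  list(fractions = best[1, ], objective = grid_objectives(S, x, best)[1])
}

## random constrained-deconvolution instance
random_qp_instance <- function(K, n_genes, noisy = TRUE) {
  S <- matrix(runif(n_genes * K, 0.1, 10), n_genes, K,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(K))))
  f <- as.numeric(stats::rmultinom(1, 100, rep(1, K))) / 100
  x <- as.numeric(S %*% f)
  if (noisy) x <- pmax(x + stats::rnorm(n_genes, sd = 0.5), 0)
  list(S = S, x = x, f_true = f)
}

## Spearman via explicit rank-then-Pearson summation
spearman_oracle <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  da <- ra - mean(ra)
  db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

## two-sided Mann-Whitney p by direct enumeration of group assignments
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  W <- sum(r[seq_len(na)])
  cb <- utils::combn(length(pooled), na)
  Ws <- colSums(matrix(r[cb], nrow = na))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

## small, fast simulation configuration for unit tests
small_sim_config <- function(...) {
  defaults <- list(
    nuclei_per_cluster = c(80, 70, 50, 40, 30),
    n_genes = 600,
    n_markers_per_cluster = 5,
    mean_genes_per_nucleus = 150,
    cohort_size = 20,
    depth = 2e5
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
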