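sig2 <- function() {
  signature_matrix(matrix(c(100, 10, 5, 3, 60, 40), 3, 2,
                          dimnames = list(paste0("g", 1:3),
                                          c("type_I", "type_II"))))
}

test_that("a pure sample is assigned fraction one with zero residual", {
  S <- sig2()
  x <- S$values[, "type_II"]
  est <- solve_proportions(S, x)
  expect_equal(est$type_II, 1)
  expect_equal(est$type_I, 0)
  expect_equal(est$type1_fraction, 0)
  expect_lt(est$residual_norm, 1e-10)
})

test_that("an exactly solvable mixture is recovered", {
  S <- matrix(c(10, 0, 5, 0, 10, 5), 3, 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  fit <- solve_simplex_ls(S, c(3, 7, 5))
  expect_equal(unname(fit$fractions), c(0.3, 0.7), tolerance = 1e-10)
  expect_lt(fit$residual_norm, 1e-10)
})

test_that("boundary-active solutions match the simplex grid oracle", {
  S <- diag(2)
  dimnames(S) <- list(c("g1", "g2"), c("A", "B"))
  fit <- solve_simplex_ls(S, c(2, 0))
  grid <- grid_search_simplex(S, c(2, 0), step = 0.001)
  expect_equal(unname(fit$fractions), c(1, 0))
  expect_equal(unname(fit$fractions), unname(grid$fractions), tolerance = 1e-9)

  set.seed(14)
  for (i in 1:40) {
    inst <- random_qp_instance(sample(2:5, 1), sample(10:50, 1))
    fit <- solve_simplex_ls(inst$S, inst$x)
    orc <- grid_oracle(inst$S, inst$x)
    expect_lte(fit$residual_norm^2, orc$objective + 1e-9)
    expect_lt(max(abs(fit$fractions - orc$fractions)), 0.002)
  }
})

test_that("solve_proportions is scale invariant and permutation equivariant", {
  set.seed(15)
  S <- sig2()
  x <- c(g1 = 40, g2 = 25, g3 = 30)
  base <- solve_proportions(S, x)
  scaled <- solve_proportions(S, 1234.5 * x)
  expect_equal(scaled$type_I, base$type_I, tolerance = 1e-10)
  expect_equal(scaled$residual_norm, base$residual_norm, tolerance = 1e-10)

  Sp <- signature_matrix(S$values[, c("type_II", "type_I")])
  perm <- solve_proportions(Sp, x)
  expect_equal(perm$type_I, base$type_I, tolerance = 1e-10)
  expect_equal(perm$type_II, base$type_II, tolerance = 1e-10)
})

test_that("noiseless mixtures are identified to 1e-6", {
  set.seed(16)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    inst <- random_qp_instance(K, sample(10:40, 1), noisy = FALSE)
    est <- solve_proportions(inst$S, stats::setNames(inst$x, rownames(inst$S)),
                             type1 = "c1", type2 = "c2")
    got <- as.numeric(est[1, paste0("c", seq_len(K))])
    expect_lt(max(abs(got - inst$f_true)), 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  S <- sig2()
  expect_error(solve_proportions(S, c(g1 = 0, g2 = 0, g3 = 0)), "all zero")
  expect_error(solve_proportions(S, c(h1 = 1, h2 = 2)), "no genes shared")
  expect_error(solve_proportions(S, c(g1 = -1, g2 = 1, g3 = 1)), "non-negative")
  Sr <- matrix(c(1, 2, 2, 4), 2, 2,
               dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(solve_simplex_ls(Sr, c(1, 2)), "rank-deficient")
})

test_that("a noiseless pseudo-bulk cohort is recovered by deconvolve_cohort", {
  S <- sig2()
  f_true <- c(0.62, 0.38)
  x <- f_true[1] * S$values[, "type_I"] + f_true[2] * S$values[, "type_II"]
  bulk <- count_matrix(matrix(x, ncol = 1,
                              dimnames = list(names(x), "sample1")), "tpm")
  est <- suppressMessages(deconvolve_cohort(S, bulk))
  expect_equal(est$type1_fraction, 0.62, tolerance = 1e-6)

  ## pure type II cohort
  pure <- count_matrix(
    matrix(S$values[, "type_II"], 3, 4,
           dimnames = list(rownames(S$values), paste0("s", 1:4))), "cpm")
  est2 <- suppressMessages(deconvolve_cohort(S, pure))
  expect_equal(est2$type1_fraction, rep(0, 4))

  ## random noiseless mixtures through the full cohort interface
  set.seed(17)
  f <- runif(30)
  mix <- sapply(f, function(fi) {
    fi * S$values[, "type_I"] + (1 - fi) * S$values[, "type_II"]
  })
  dimnames(mix) <- list(rownames(S$values), sprintf("m%02d", 1:30))
  est3 <- suppressMessages(deconvolve_cohort(S, count_matrix(mix, "tpm")))
  expect_lt(max(abs(est3$type1_fraction - f)), 1e-6)
})

test_that("gene overlap policing works and fiber_only uses fiber markers", {
  set.seed(18)
  genes <- paste0("g", 1:10)
  S <- signature_matrix(
    matrix(runif(30, 1, 10), 10, 3,
           dimnames = list(genes, c("type_I", "type_II", "endothelial"))),
    markers = tibble::tibble(gene = genes,
                             cluster = rep(c("type_I", "type_II", "endothelial"),
                                           c(4, 4, 2)))
  )
  bulk_few <- count_matrix(
    matrix(runif(8, 1, 5), 2, 4,
           dimnames = list(genes[1:2], paste0("s", 1:4))), "cpm")
  expect_error(suppressMessages(deconvolve_cohort(S, bulk_few)), "signature genes")
  expect_warning(
    suppressMessages(
      deconvolve_cohort(S, bulk_few, on_low_overlap = "warn", type2 = "type_II")
    ),
    "signature genes"
  )

  full <- count_matrix(
    matrix(runif(40, 1, 5), 10, 4, dimnames = list(genes, paste0("s", 1:4))),
    "cpm")
  fib <- suppressMessages(deconvolve_cohort(S, full, mode = "fiber_only"))
  expect_equal(unique(fib$n_genes_used), 8L)  # fiber markers only
  expect_setequal(attr(fib, "clusters"), c("type_I", "type_II"))
  allc <- suppressMessages(deconvolve_cohort(S, full, mode = "all_clusters"))
  expect_equal(unique(allc$n_genes_used), 10L)
  expect_true(all(abs(allc$type_I + allc$type_II + allc$endothelial - 1) < 1e-8))
  ## type I fraction is the renormalized fiber share
  expect_equal(allc$type1_fraction,
               allc$type_I / (allc$type_I + allc$type_II), tolerance = 1e-12)
})
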