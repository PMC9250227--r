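#' Log-normalize a count matrix
#'
#' The standard single-cell "LogNormalize": each entry `c` in a column with
#' total `T` becomes `ln(1 + c * scale_factor / T)`. Natural logarithm;
#' default scale factor 1e4. Zero stays zero, so sparsity is preserved.
#'
#' @param m A [count_matrix()] in a count unit.
#' @param scale_factor Positive pseudo-library size (default `1e4`).
#' @return A [count_matrix()] with unit `"lognorm"`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  assert_count_matrix(m, units = c("umi_counts", "read_counts"))
  stopifnot(is.numeric(scale_factor), scale_factor > 0)
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0)) abort("log_normalize: column(s) with zero total counts.")
  v <- scale_columns(m$values, scale_factor / totals)
  if (methods::is(v, "sparseMatrix")) {
    v@x <- log1p(v@x)
  } else {
    v <- log1p(v)
  }
  count_matrix(v, "lognorm")
}

## multiply column j by s[j], keeping sparsity and dimnames
scale_columns <- function(v, s) {
  out <- if (methods::is(v, "sparseMatrix")) {
    v %*% Matrix::Diagonal(x = s)
  } else {
    sweep(v, 2, s, "*")
  }
  dimnames(out) <- dimnames(v)
  out
}

#' Counts-per-million normalization
#'
#' Scales every column to sum to 1e6 (linear scale). Used per nucleus before
#' averaging cluster signatures and per sample before deconvolution.
#'
#' @param m A [count_matrix()] in a count unit.
#' @return A [count_matrix()] with unit `"cpm"`.
#' @export
cpm_normalize <- function(m) {
  assert_count_matrix(m, units = c("umi_counts", "read_counts"))
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0)) abort("cpm_normalize: column(s) with zero total counts.")
  v <- scale_columns(m$values, 1e6 / totals)
  dimnames(v) <- dimnames(m$values)
  count_matrix(v, "cpm")
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes one between-library scaling factor per sample by the TMM recipe:
#' against a reference column, genewise log2 ratios (M) and average log2
#' abundances (A) are formed over the genes positive in both libraries; the
#' most extreme 30% of M values (each tail) and 5% of A values are trimmed;
#' the factor is 2 to the inverse-asymptotic-variance-weighted mean of the
#' surviving M values. Factors are renormalized so their log-mean is zero
#' (product 1), hence two identical libraries both get factor exactly 1.
#'
#' M and A are computed on raw counts, so the returned factor is the full
#' between-library scaling (library size times compositional correction);
#' dividing each column by its factor puts all libraries on a common scale.
#'
#' @param m A [count_matrix()] of counts with at least two columns.
#' @param ref_column Observation id of the reference library, or `NULL` to
#'   pick the column whose upper-quartile count fraction is closest to the
#'   mean upper quartile.
#' @param trim_m,trim_a Two-tailed trim fractions for M and A (defaults 0.30
#'   and 0.05, the published TMM defaults).
#' @return Named numeric vector of positive factors, one per column, with
#'   geometric mean 1.
#' @export
tmm_factors <- function(m, ref_column = NULL, trim_m = 0.30, trim_a = 0.05) {
  assert_count_matrix(m, units = c("umi_counts", "read_counts"))
  v <- as.matrix(m$values)
  if (ncol(v) < 2L) abort("tmm_factors needs at least two libraries.")
  lib <- colSums(v)
  if (any(lib == 0)) abort("tmm_factors: column(s) with zero total counts.")
  if (is.null(ref_column)) {
    f75 <- apply(v, 2, stats::quantile, probs = 0.75) / lib
    ref_column <- colnames(v)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref_column %in% colnames(v)) abort("unknown `ref_column`.")
  ref <- v[, ref_column]
  nR <- sum(ref)
  f <- vapply(seq_len(ncol(v)), function(j) {
    tmm_pair_factor(v[, j], ref, sum(v[, j]), nR, trim_m, trim_a)
  }, numeric(1))
  names(f) <- colnames(v)
  f / exp(mean(log(f)))
}

## one library vs the reference. M and A are formed on library-size-normalized
## counts (the classical definition); the library-size log-ratio is added back
## to the trimmed weighted mean so the returned factor is the full raw-count
## scaling. The shift is a per-library constant, so trimming is unaffected.
tmm_pair_factor <- function(obs, ref, nO, nR, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) abort("tmm_factors: no genes positive in both libraries.")
  obs <- obs[keep]
  ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  ## asymptotic variance of M (delta method, binomial counts)
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  shift <- log2(nO / nR)
  if (max(abs(M)) < 1e-6) return(2^shift)  # libraries proportional
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) abort("tmm_factors: no genes survive trimming.")
  w <- pmax(w, .Machine$double.eps)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]) + shift)
}
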