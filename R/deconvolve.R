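#' Least squares on the probability simplex (active-set QP)
#'
#' Solves `min ||x - S f||_2` subject to `f >= 0` and `sum(f) = 1`, the
#' constrained linear decomposition at the core of reference-based
#' deconvolution. The solver is an exact primal active-set quadratic program:
#' starting from the uniform feasible point, equality-constrained KKT systems
#' are solved on the free variables, bounds that block the step are activated,
#' and active bounds with negative multipliers are released until the KKT
#' conditions hold. The procedure is deterministic and terminates at the
#' unique global minimizer (the objective is strictly convex when `S` has
#' full column rank).
#'
#' @param S Numeric matrix, genes x clusters, full column rank.
#' @param x Numeric vector of length `nrow(S)`.
#' @param tol Feasibility/optimality tolerance (default 1e-10).
#' @return List with `fractions` (non-negative, summing to 1), `residual_norm`
#'   (the attained `||x - S f||_2`) and `iterations`.
#' @export
solve_simplex_ls <- function(S, x, tol = 1e-10) {
  S <- as.matrix(S)
  x <- as.numeric(x)
  if (length(x) != nrow(S)) abort("length(x) must equal nrow(S).")
  K <- ncol(S)
  if (K == 1L) {
    f <- stats::setNames(1, colnames(S))
    return(list(fractions = f, residual_norm = sqrt(sum((x - S[, 1])^2)),
                iterations = 0L))
  }
  if (qr(S)$rank < K) abort("signature matrix is rank-deficient on the used genes.")
  Q <- crossprod(S)
  d <- drop(crossprod(S, x))
  f <- rep(1 / K, K)
  active <- rep(FALSE, K)
  max_iter <- 50L * K
  for (it in seq_len(max_iter)) {
    free <- which(!active)
    kk <- length(free)
    KKT <- rbind(cbind(Q[free, free, drop = FALSE], -1), c(rep(1, kk), 0))
    sol <- solve(KKT, c(d[free], 1))
    f_new <- numeric(K)
    f_new[free] <- sol[seq_len(kk)]
    lambda <- sol[kk + 1]
    if (min(f_new[free]) >= -tol) {
      f <- f_new
      if (!any(active)) break
      mu <- (Q %*% f - d)[active] - lambda
      if (min(mu) >= -tol) break
      rel <- which(active)[which.min(mu)]
      active[rel] <- FALSE
    } else {
      step <- f_new - f
      blocking <- which(step < -tol & f > 0 & !active)
      alpha <- f[blocking] / -step[blocking]
      j <- blocking[which.min(alpha)]
      f <- f + min(alpha) * step
      f[j] <- 0
      active[j] <- TRUE
    }
    if (it == max_iter) abort("active-set QP failed to converge.")
  }
  f[f < 0] <- 0
  f <- f / sum(f)
  names(f) <- colnames(S)
  list(fractions = f, residual_norm = sqrt(sum((x - S %*% f)^2)),
       iterations = it)
}

## standardize x and the columns of S to unit total; returns pieces needed
## to map simplex weights back to original-scale mixing fractions
standardize_for_fit <- function(S, x) {
  tot_S <- colSums(S)
  if (any(tot_S <= 0)) abort("signature column(s) with zero total over the used genes.")
  tot_x <- sum(x)
  if (tot_x <= 0) abort("bulk expression vector is all zero over the used genes.")
  list(S = sweep(S, 2, tot_S, "/"), x = x / tot_x, tot_S = tot_S)
}

#' Infer cluster proportions for one bulk sample
#'
#' Fits the mixing model `x ~ S f` on the genes shared between the signature
#' and the bulk vector. Both `x` and the columns of `S` are scaled to unit
#' total over the shared genes before solving (making the fit invariant to
#' the expression unit and to any positive rescaling of `x`); the simplex
#' weights are then mapped back through the signature column totals so the
#' returned fractions are mixing weights of the original signature columns.
#' Under a noiseless mixture `x = S f*` the solver returns `f*` exactly (up
#' to numerical tolerance).
#'
#' @param S A [signature_matrix()] (or bare genes x clusters matrix).
#' @param x Named non-negative numeric vector of bulk expression; names are
#'   matched to the signature genes after stripping version suffixes.
#' @param type1,type2 Cluster ids of the slow- and fast-twitch fiber columns,
#'   used to derive `type1_fraction = f_I / (f_I + f_II)`; `NA` if either
#'   column is absent.
#' @return One-row tibble: `fractions` per cluster (one column per cluster),
#'   `type1_fraction`, `residual_norm` (on the standardized scale) and
#'   `n_genes_used`.
#' @export
solve_proportions <- function(S, x, type1 = "type_I", type2 = "type_II") {
  Sm <- if (inherits(S, "signature_matrix")) S$values else as.matrix(S)
  if (is.null(names(x))) abort("`x` must be a named vector of gene expression.")
  if (min(x) < 0) abort("`x` must be non-negative.")
  idx <- match(strip_gene_version(rownames(Sm)), strip_gene_version(names(x)))
  used <- !is.na(idx)
  if (!any(used)) abort("no genes shared between the signature and `x`.")
  Sm <- Sm[used, , drop = FALSE]
  xv <- as.numeric(x)[idx[used]]
  std <- standardize_for_fit(Sm, xv)
  fit <- solve_simplex_ls(std$S, std$x)
  g <- fit$fractions
  f <- (g / std$tot_S)
  f <- f / sum(f)
  res <- as_tibble(as.list(f))
  res$type1_fraction <- type1_fraction_of(f, type1, type2)
  res$residual_norm <- fit$residual_norm
  res$n_genes_used <- sum(used)
  res
}

type1_fraction_of <- function(f, type1, type2) {
  if (!(type1 %in% names(f)) || !(type2 %in% names(f))) return(NA_real_)
  tot <- f[[type1]] + f[[type2]]
  if (tot <= 0) return(NA_real_)
  f[[type1]] / tot
}

#' Deconvolve a bulk cohort into cluster proportions
#'
#' Applies [solve_proportions()] to every sample of a bulk expression matrix.
#' Count-unit input is CPM-converted first. Genes present in the signature
#' but absent from the bulk table are dropped (absent quantification is not
#' evidence of zero expression); if fewer than `min_overlap` of the signature
#' genes are found this is an error (downgradeable to a warning).
#'
#' In `fiber_only` mode (the default, matching a two-fiber-cluster depth
#' analysis) the signature is restricted to the type I and type II columns
#' and, when the signature carries a marker-cluster map, to their own marker
#' genes before solving. `all_clusters` mode fits all columns and derives the
#' type I fraction from the two fiber columns renormalized.
#'
#' @param S A [signature_matrix()].
#' @param bulk A [count_matrix()] of the cohort (counts, CPM or TPM).
#' @param mode `"fiber_only"` or `"all_clusters"`.
#' @param type1,type2 Fiber cluster ids in `S`.
#' @param min_overlap Minimum fraction of signature genes that must be found
#'   in the bulk table (default 0.5).
#' @param on_low_overlap `"error"` (default) or `"warn"`.
#' @return A tibble of class `fiber_proportions`: one row per sample with
#'   `sample_id`, one fraction column per fitted cluster, `type1_fraction`,
#'   `residual_norm`, `n_genes_used`.
#' @export
deconvolve_cohort <- function(S, bulk, mode = c("fiber_only", "all_clusters"),
                              type1 = "type_I", type2 = "type_II",
                              min_overlap = 0.5,
                              on_low_overlap = c("error", "warn")) {
  mode <- match.arg(mode)
  on_low_overlap <- match.arg(on_low_overlap)
  stopifnot(inherits(S, "signature_matrix"))
  assert_count_matrix(bulk, units = c("umi_counts", "read_counts", "cpm", "tpm"),
                      arg = "bulk")
  if (is_count_unit(bulk)) bulk <- cpm_normalize(bulk)
  Sm <- S$values
  if (mode == "fiber_only") {
    fiber <- c(type1, type2)
    if (!all(fiber %in% colnames(Sm))) {
      abort(sprintf("fiber clusters '%s'/'%s' not found in the signature.", type1, type2))
    }
    Sm <- Sm[, fiber, drop = FALSE]
    if (!is.null(S$markers)) {
      fg <- unique(S$markers$gene[S$markers$cluster %in% fiber])
      if (length(fg) >= 2) Sm <- Sm[rownames(Sm) %in% fg, , drop = FALSE]
    }
    Sm <- Sm[rowSums(Sm) > 0, , drop = FALSE]
  }
  hit <- strip_gene_version(rownames(Sm)) %in% strip_gene_version(gene_ids(bulk))
  overlap <- mean(hit)
  if (overlap < min_overlap) {
    msg <- sprintf(
      "only %d/%d (%.0f%%) signature genes found in the bulk table.",
      sum(hit), length(hit), 100 * overlap
    )
    if (on_low_overlap == "error") abort(msg) else warn(msg)
  }
  if (sum(hit) < length(hit)) {
    inform(sprintf("dropping %d signature gene(s) absent from the bulk table.",
                   sum(!hit)))
  }
  Sm <- Sm[hit, , drop = FALSE]
  Ssub <- signature_matrix(Sm, unit = S$unit)
  bm <- as.matrix(bulk$values)
  rows <- lapply(obs_ids(bulk), function(s) {
    est <- solve_proportions(Ssub, bm[, s], type1 = type1, type2 = type2)
    dplyr::bind_cols(tibble(sample_id = s), est)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "clusters") <- colnames(Sm)
  attr(out, "type1") <- type1
  attr(out, "type2") <- type2
  class(out) <- c("fiber_proportions", class(out))
  out
}

#' @method tidy fiber_proportions
#' @export
tidy.fiber_proportions <- function(x, ...) {
  cl <- attr(x, "clusters")
  tidyr::pivot_longer(as_tibble(x)[, c("sample_id", cl)],
                      cols = dplyr::all_of(cl),
                      names_to = "cluster", values_to = "fraction")
}

#' @method glance fiber_proportions
#' @export
glance.fiber_proportions <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    mean_type1_fraction = mean(x$type1_fraction),
    median_type1_fraction = stats::median(x$type1_fraction),
    mean_residual_norm = mean(x$residual_norm),
    mode = attr(x, "mode")
  )
}
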