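#' Specification of a depth-robustness experiment
#'
#' @param depths Strictly increasing positive target read totals per sample
#'   (default: 7 logarithmically spaced points from 1e4 to 1e7).
#' @param seed Integer seed; all thinning randomness derives from it.
#' @param replicates Number of independent thinning replicates per depth.
#' @return A list of class `downsample_spec`.
#' @export
downsample_spec <- function(depths = 10^seq(4, 7, length.out = 7),
                            seed = 1L, replicates = 10L) {
  depths <- as.numeric(depths)
  if (length(depths) == 0L || any(depths <= 0) || is.unsorted(depths, strictly = TRUE)) {
    abort("`depths` must be positive and strictly increasing.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  structure(list(depths = depths, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "downsample_spec")
}

#' Binomially thin a count matrix to a target depth
#'
#' Emulates random read subsampling at the count level: each count `c` in a
#' sample with total `T` is replaced by a Binomial(`c`, `target_depth / T`)
#' draw. Per-gene counts under read subsampling without replacement are
#' hypergeometric; at sequencing scale the binomial is an excellent match and
#' keeps the experiment desk-scale. Samples whose total is already at or
#' below the target pass through unchanged with a warning.
#'
#' @param bulk A [count_matrix()] of integer counts.
#' @param target_depth Positive target total per sample.
#' @param seed Integer seed; the draw is a pure function of
#'   `(bulk, target_depth, seed)`.
#' @return A thinned [count_matrix()] (same unit) with attribute
#'   `realized_totals`.
#' @export
thin_counts <- function(bulk, target_depth, seed) {
  assert_count_matrix(bulk, units = c("umi_counts", "read_counts"), arg = "bulk")
  stopifnot(is.numeric(target_depth), target_depth > 0)
  v <- as.matrix(bulk$values)
  if (max(abs(v - round(v))) > 1e-8) {
    abort("thin_counts requires integer-valued counts.")
  }
  v <- round(v)
  totals <- colSums(v)
  p <- pmin(1, target_depth / totals)
  if (any(totals <= target_depth)) {
    warn(sprintf(
      "%d sample(s) at or below the target depth pass through unchanged.",
      sum(totals <= target_depth)
    ))
  }
  out <- withr::with_seed(as.integer(seed), {
    thinned <- v
    for (j in seq_len(ncol(v))) {
      if (p[j] < 1) {
        thinned[, j] <- stats::rbinom(nrow(v), size = v[, j], prob = p[j])
      }
    }
    thinned
  })
  res <- count_matrix(out, bulk$unit)
  attr(res, "realized_totals") <- colSums(out)
  res
}

#' Accuracy of fiber-fraction inference across sequencing depths
#'
#' For every depth and replicate: thin the cohort, deconvolve in `fiber_only`
#' mode, and score the estimated type I fractions against the truth with the
#' Spearman correlation and the mean square deviation. When `truth` is not
#' given, the full-depth predictions serve as the reference, so the curve
#' measures pure depth-induced degradation.
#'
#' @param S A [signature_matrix()].
#' @param bulk A [count_matrix()] of integer counts, one column per sample.
#' @param spec A [downsample_spec()].
#' @param truth Optional tibble `(sample_id, type1_fraction)`; defaults to
#'   the full-depth predictions.
#' @param type1,type2 Fiber cluster ids in `S`.
#' @return A tibble of class `downsample_curve`: one row per
#'   `(depth, replicate)` with `spearman_r`, `mean_square_deviation`, and the
#'   per-sample realized totals as a list column (`realized_totals`).
#'   Spearman is `NA` when either vector is constant (undefined, never
#'   fabricated).
#' @export
depth_robustness <- function(S, bulk, spec = downsample_spec(), truth = NULL,
                             type1 = "type_I", type2 = "type_II") {
  stopifnot(inherits(spec, "downsample_spec"))
  assert_count_matrix(bulk, units = c("umi_counts", "read_counts"), arg = "bulk")
  if (is.null(truth)) {
    full <- deconvolve_cohort(S, bulk, mode = "fiber_only",
                              type1 = type1, type2 = type2)
    truth <- tibble(sample_id = full$sample_id,
                    type1_fraction = full$type1_fraction)
  }
  truth <- as_tibble(truth)[, c("sample_id", "type1_fraction")]
  if (!all(obs_ids(bulk) %in% truth$sample_id)) {
    abort("`truth` must cover every sample of the cohort.")
  }
  ref <- truth$type1_fraction[match(obs_ids(bulk), truth$sample_id)]
  grid <- tidyr::expand_grid(depth_i = seq_along(spec$depths),
                             replicate = seq_len(spec$replicates))
  rows <- pmap(grid, function(depth_i, replicate) {
    depth <- spec$depths[depth_i]
    sub_seed <- (spec$seed + 7919L * depth_i + 104729L * replicate) %% .Machine$integer.max
    thinned <- suppressWarnings(thin_counts(bulk, depth, seed = sub_seed))
    est <- deconvolve_cohort(S, thinned, mode = "fiber_only",
                             type1 = type1, type2 = type2)
    pred <- est$type1_fraction[match(obs_ids(bulk), est$sample_id)]
    r <- if (safe_sd(pred) == 0 || safe_sd(ref) == 0) {
      NA_real_
    } else {
      stats::cor(pred, ref, method = "spearman")
    }
    tibble(
      depth = depth, replicate = replicate,
      spearman_r = r,
      mean_square_deviation = mean_square_deviation(pred, ref),
      realized_totals = list(attr(thinned, "realized_totals"))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- spec$seed
  class(out) <- c("downsample_curve", class(out))
  out
}

safe_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' @method glance downsample_curve
#' @export
glance.downsample_curve <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$depth),
    mean_spearman_r = mean(.data$spearman_r, na.rm = TRUE),
    mean_msd = mean(.data$mean_square_deviation),
    .groups = "drop"
  )
}
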