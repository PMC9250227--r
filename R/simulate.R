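#' Configuration of the synthetic muscle reference and cohort generator
#'
#' The defaults emulate the shape of a human skeletal-muscle single-nuclei
#' reference: five clusters (fast-twitch type II and slow-twitch type I fiber
#' nuclei dominating, plus fibroblast-like, endothelial and pericyte-like
#' populations), 2699 nuclei, 2000 genes with lognormal abundance, 10 planted
#' markers per cluster at fold change 8, negative-binomial UMI counts, and
#' per-nucleus library sizes calibrated so the median number of detected
#' genes per nucleus is about 500. Marker genes are given high baseline
#' abundance (the 95th percentile of the gene-mean distribution): sarcomeric
#' transcripts dominate muscle libraries, and this is what makes shallow
#' sequencing informative.
#'
#' Pseudo-bulk cohorts draw each sample's type I fraction from a Beta
#' distribution; the default single group has mode 0.62 (the typical mean
#' type I share of vastus lateralis in young men), and [sex_fraction_groups()]
#' provides a two-group preset with modes 0.68 (women-like) and 0.56
#' (men-like).
#'
#' @param n_clusters Number of clusters (>= 2; first two are the fiber types).
#' @param nuclei_per_cluster Integer vector of cluster sizes (recycled or
#'   truncated to `n_clusters`).
#' @param n_genes Total number of genes.
#' @param n_markers_per_cluster Planted markers per cluster.
#' @param marker_fold_change Mean multiplier of a marker in its home cluster
#'   (> 1 for informative markers; 1 gives a null simulation).
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param mean_genes_per_nucleus Target median detected genes per nucleus.
#' @param gene_mean_sdlog Lognormal sd of baseline gene abundance.
#' @param libsize_sdlog Lognormal sd of per-nucleus library size.
#' @param cohort_size Number of pseudo-bulk samples.
#' @param depth Reads per pseudo-bulk sample.
#' @param contamination Fraction of each bulk profile contributed by the
#'   first non-fiber cluster (0 disables).
#' @param fraction_distribution Tibble with columns `group`, `mode`,
#'   `concentration`, `n` describing per-group Beta distributions of the
#'   type I fraction (`n = NA` splits `cohort_size` equally).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_clusters = 5,
                              nuclei_per_cluster = c(900, 750, 450, 400, 199),
                              n_genes = 2000,
                              n_markers_per_cluster = 10,
                              marker_fold_change = 8,
                              nb_dispersion = 0.8,
                              mean_genes_per_nucleus = 500,
                              gene_mean_sdlog = 1.2,
                              libsize_sdlog = 0.35,
                              cohort_size = 50,
                              depth = 1e6,
                              contamination = 0,
                              fraction_distribution = NULL) {
  stopifnot(
    n_clusters >= 2, n_genes >= 10, n_markers_per_cluster >= 1,
    marker_fold_change >= 1, nb_dispersion > 0, mean_genes_per_nucleus >= 1,
    cohort_size >= 1, depth >= 1, contamination >= 0, contamination < 1
  )
  nuclei_per_cluster <- rep_len(as.integer(nuclei_per_cluster), n_clusters)
  if (any(nuclei_per_cluster < 1)) abort("cluster sizes must be positive.")
  if (is.null(fraction_distribution)) {
    fraction_distribution <- tibble(group = "all", mode = 0.62,
                                    concentration = 20, n = NA_integer_)
  }
  fraction_distribution <- as_tibble(fraction_distribution)
  stopifnot(all(c("group", "mode", "concentration", "n") %in%
                  names(fraction_distribution)))
  if (any(fraction_distribution$mode <= 0 | fraction_distribution$mode >= 1) ||
      any(fraction_distribution$concentration <= 2)) {
    abort("Beta modes must lie in (0,1) and concentrations exceed 2.")
  }
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      nuclei_per_cluster = nuclei_per_cluster,
      n_genes = as.integer(n_genes),
      n_markers_per_cluster = as.integer(n_markers_per_cluster),
      marker_fold_change = marker_fold_change,
      nb_dispersion = nb_dispersion,
      mean_genes_per_nucleus = mean_genes_per_nucleus,
      gene_mean_sdlog = gene_mean_sdlog,
      libsize_sdlog = libsize_sdlog,
      cohort_size = as.integer(cohort_size),
      depth = depth,
      contamination = contamination,
      fraction_distribution = fraction_distribution
    ),
    class = "simulation_config"
  )
}

#' Two-group Beta preset for sex differences in type I fraction
#'
#' Women-like and men-like groups with Beta modes 0.68 and 0.56 and sizes
#' 171 and 398, the reported medians and group sizes for vastus lateralis in
#' a large population cohort. Concentrations are set so the central 95% mass
#' roughly spans 0.53-0.81 and 0.36-0.75.
#'
#' @return Tibble usable as `fraction_distribution` in [simulation_config()].
#' @export
sex_fraction_groups <- function() {
  tibble(group = c("women", "men"), mode = c(0.68, 0.56),
         concentration = c(40, 25), n = c(171L, 398L))
}

sim_cluster_names <- function(K) {
  base <- c("type_II", "type_I", "fibroblast_like", "endothelial", "pericyte_like")
  if (K <= length(base)) base[seq_len(K)] else c(base, paste0("other_", seq_len(K - length(base))))
}

## gene id layout: real marker symbols where the literature names them,
## synthetic MRK ids for the rest, real-prefixed mito/ribo ids, G filler
sim_gene_ids <- function(cfg, clusters) {
  named <- bundled_fiber_markers()
  mk_ids <- lapply(clusters, function(k) {
    real <- if (k %in% names(named)) named[[k]] else character(0)
    real <- real[seq_len(min(length(real), cfg$n_markers_per_cluster))]
    extra <- cfg$n_markers_per_cluster - length(real)
    c(real, if (extra > 0) sprintf("MRK_%s_%02d", k, seq_len(extra)))
  })
  names(mk_ids) <- clusters
  mito <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
            "MT-ND6", "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8",
            "MT-CYB")
  ribo <- c(sprintf("RPL%d", 1:10), sprintf("RPS%d", 1:10))
  used <- length(unlist(mk_ids)) + length(mito) + length(ribo)
  if (used >= cfg$n_genes) abort("n_genes too small for the marker/mito/ribo layout.")
  filler <- sprintf("G%04d", seq_len(cfg$n_genes - used))
  list(markers = mk_ids, mito = mito, ribo = ribo,
       all = c(unlist(mk_ids, use.names = FALSE), mito, ribo, filler))
}

#' Generate a synthetic labeled single-nuclei reference
#'
#' Per-cluster negative-binomial UMI counts over a lognormal gene-abundance
#' baseline; each cluster's planted markers have their mean multiplied by the
#' configured fold change in their home cluster. Library sizes are calibrated
#' by root finding so the median number of detected genes per nucleus matches
#' the target. Mitochondrial- and ribosomal-prefixed genes are included at
#' modest abundance so quality-control filters are exercisable on the output.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; the output is a pure function of `(cfg, seed)`.
#' @return List with `counts` (a [count_matrix()] of UMI counts), `labels`
#'   (a [cluster_labeling()]), `markers` (tibble of planted `gene`,
#'   `cluster`), and `profiles` (a [signature_matrix()] of true mean CPM per
#'   cluster over all genes, carrying the planted marker map).
#' @export
generate_reference <- function(cfg = simulation_config(), seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  clusters <- sim_cluster_names(cfg$n_clusters)
  layout <- sim_gene_ids(cfg, clusters)
  gid <- layout$all
  G <- cfg$n_genes
  withr::with_seed(as.integer(seed), {
    base <- stats::rlnorm(G, meanlog = 0, sdlog = cfg$gene_mean_sdlog)
    names(base) <- gid
    ## abundant marker baseline: sarcomeric transcripts dominate muscle
    marker_level <- exp(cfg$gene_mean_sdlog * stats::qnorm(0.95))
    base[unlist(layout$markers, use.names = FALSE)] <- marker_level
    base[layout$mito] <- base[layout$mito] * 3
    fold <- matrix(1, G, cfg$n_clusters, dimnames = list(gid, clusters))
    for (k in clusters) fold[layout$markers[[k]], k] <- cfg$marker_fold_change
    prof <- sweep(base * fold, 2, colSums(base * fold), "/")

    ## calibrate the median library size against median detected genes
    pbar <- drop(prof %*% (cfg$nuclei_per_cluster / sum(cfg$nuclei_per_cluster)))
    theta <- cfg$nb_dispersion
    detect_at <- function(L) sum(1 - (theta / (theta + L * pbar))^theta)
    target <- min(cfg$mean_genes_per_nucleus, 0.95 * G)
    if (target < cfg$mean_genes_per_nucleus) {
      warn(sprintf("detection target capped at %.0f of %d genes.", target, G))
    }
    L0 <- stats::uniroot(function(L) detect_at(L) - target,
                         lower = 1, upper = 1e9, tol = 1e-3)$root

    n_total <- sum(cfg$nuclei_per_cluster)
    counts <- matrix(0L, G, n_total)
    labs <- character(n_total)
    col <- 0L
    for (j in seq_along(clusters)) {
      for (i in seq_len(cfg$nuclei_per_cluster[j])) {
        col <- col + 1L
        L <- stats::rlnorm(1, meanlog = log(L0), sdlog = cfg$libsize_sdlog)
        counts[, col] <- stats::rnbinom(G, size = theta, mu = L * prof[, j])
        labs[col] <- clusters[j]
      }
    }
    dimnames(counts) <- list(gid, sprintf("N%04d", seq_len(n_total)))
    achieved <- stats::median(colSums(counts > 0))
    if (abs(achieved - target) > 0.2 * target) {
      warn(sprintf(
        "library-size calibration off target: median %.1f detected genes vs target %.0f.",
        achieved, target
      ))
    }
    markers <- dplyr::bind_rows(imap(layout$markers,
                                     function(g, k) tibble(gene = g, cluster = k)))
    profiles <- signature_matrix(prof * 1e6, markers = markers, unit = "cpm")
    list(
      counts = count_matrix(Matrix::Matrix(counts, sparse = TRUE), "umi_counts"),
      labels = cluster_labeling(colnames(counts), labs),
      markers = markers,
      profiles = profiles
    )
  })
}

## resolve per-group sample counts
resolve_groups <- function(fd, cohort_size) {
  n <- fd$n
  if (all(is.na(n))) {
    n <- rep(cohort_size %/% nrow(fd), nrow(fd))
    n[1] <- n[1] + cohort_size - sum(n)
  }
  if (anyNA(n) || any(n < 1)) abort("group sizes must all be given or all NA.")
  as.integer(n)
}

#' Generate a pseudo-bulk cohort with known fiber fractions
#'
#' Each sample draws its type I fraction `f` from its group's Beta
#' distribution, forms the expected expression profile
#' `f * s_I + (1 - f) * s_II` from the unit-scaled type I / type II signature
#' columns (plus an optional non-fiber contamination term), and samples reads
#' multinomially at the configured depth. This makes read sampling in the
#' cohort consistent with the binomial thinning used by [thin_counts()].
#'
#' @param S_true A [signature_matrix()] with `type_I` and `type_II` columns
#'   (e.g. the `profiles` of [generate_reference()]), or the reference list
#'   itself.
#' @param cfg A [simulation_config()] (cohort fields: `cohort_size`, `depth`,
#'   `contamination`, `fraction_distribution`).
#' @param seed Integer seed.
#' @return List with `bulk` (a [count_matrix()] of read counts), `truth`
#'   (tibble `sample_id`, `type1_fraction`, `group`), and `groups`.
#' @export
generate_cohort <- function(S_true, cfg = simulation_config(), seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.list(S_true) && !inherits(S_true, "signature_matrix") &&
      !is.null(S_true$profiles)) {
    S_true <- S_true$profiles
  }
  stopifnot(inherits(S_true, "signature_matrix"))
  Sm <- S_true$values
  if (!all(c("type_I", "type_II") %in% colnames(Sm))) {
    abort("`S_true` must contain 'type_I' and 'type_II' columns.")
  }
  if (cfg$depth < 1) abort("`depth` must be >= 1.")
  s1 <- Sm[, "type_I"] / sum(Sm[, "type_I"])
  s2 <- Sm[, "type_II"] / sum(Sm[, "type_II"])
  contam <- NULL
  if (cfg$contamination > 0) {
    extra <- setdiff(colnames(Sm), c("type_I", "type_II"))
    if (length(extra) == 0L) abort("contamination requested but no non-fiber column.")
    contam <- Sm[, extra[1]] / sum(Sm[, extra[1]])
  }
  fd <- cfg$fraction_distribution
  n_g <- resolve_groups(fd, cfg$cohort_size)
  withr::with_seed(as.integer(seed), {
    group <- rep(fd$group, n_g)
    f <- unlist(map2(seq_len(nrow(fd)), n_g, function(i, n) {
      k <- fd$concentration[i]
      a <- fd$mode[i] * (k - 2) + 1
      b <- (1 - fd$mode[i]) * (k - 2) + 1
      stats::rbeta(n, a, b)
    }))
    n_samp <- length(f)
    ids <- sprintf("S%03d", seq_len(n_samp))
    counts <- matrix(0L, nrow(Sm), n_samp, dimnames = list(rownames(Sm), ids))
    for (i in seq_len(n_samp)) {
      e <- f[i] * s1 + (1 - f[i]) * s2
      if (!is.null(contam)) e <- (1 - cfg$contamination) * e + cfg$contamination * contam
      counts[, i] <- stats::rmultinom(1, size = cfg$depth, prob = e)
    }
    list(
      bulk = count_matrix(counts, "read_counts"),
      truth = tibble(sample_id = ids, type1_fraction = f, group = group),
      groups = group
    )
  })
}
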