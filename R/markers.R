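#' Detect cluster marker genes by one-vs-rest rank-sum tests
#'
#' For every cluster, each gene is tested with a two-sided Wilcoxon rank-sum
#' test of its log-normalized expression in the cluster against all other
#' nuclei. P-values are Benjamini-Hochberg adjusted within each cluster's test
#' family. A gene is reported as a marker of a cluster when it passes the
#' log-fold-change, detection-fraction and adjusted-p thresholds.
#'
#' The log fold change is `ln(mean(expm1(in)) + 1) - ln(mean(expm1(out)) + 1)`
#' (means of de-logged expression with pseudocount 1), which is stable for
#' zero-heavy single-nuclei data. Exact permutation p-values (midranks) are
#' used when the group sizes permit full enumeration; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param m A [count_matrix()] with unit `"lognorm"` (see [log_normalize()]).
#' @param labels A [cluster_labeling()] covering the observations of `m`;
#'   at least two clusters, each with at least two nuclei (single-nucleus
#'   clusters are skipped with a warning: the rank test is undefined there).
#' @param min_lfc Minimum natural-log fold change (default 0.25).
#' @param min_pct_in Minimum fraction of in-cluster nuclei detecting the gene
#'   (default 0.1).
#' @param max_adj_p Maximum BH-adjusted p-value (default 0.05).
#' @param top_n Optional cap on markers returned per cluster (after sorting
#'   by ascending adjusted p, then descending fold change, ties broken by
#'   gene id).
#' @return A tibble of class `marker_table` with columns `gene`, `cluster`,
#'   `log_fold_change`, `pct_in`, `pct_out`, `p_value`, `adj_p_value`.
#' @export
find_markers <- function(m, labels, min_lfc = 0.25, min_pct_in = 0.1,
                         max_adj_p = 0.05, top_n = NULL) {
  assert_count_matrix(m, units = "lognorm")
  stopifnot(inherits(labels, "cluster_labeling"))
  assert_labels_match(m, labels)
  cl <- cluster_ids(labels)
  if (length(cl) < 2L) abort("find_markers needs at least two clusters.")
  sizes <- table(labels$cluster)
  if (any(sizes == 0)) abort("every cluster must contain at least one nucleus.")
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf(
      "skipping single-nucleus cluster(s): %s (rank test undefined).",
      paste(small, collapse = ", ")
    ))
    cl <- setdiff(cl, small)
    if (length(cl) < 2L) abort("fewer than two testable clusters remain.")
  }

  v <- as.matrix(m$values[, labels$obs_id, drop = FALSE])
  G <- nrow(v)
  N <- ncol(v)
  memb <- vapply(cl, function(k) labels$cluster == k, logical(N))  # N x K
  n_k <- colSums(memb)

  ## one ranking per gene serves every cluster's one-vs-rest test
  ranks <- matrix(0, G, N)
  tie_terms <- numeric(G)
  for (g in seq_len(G)) {
    r <- rank(v[g, ])
    ranks[g, ] <- r
    tt <- rle(sort(r))$lengths
    tie_terms[g] <- sum(tt^3 - tt)
  }

  W <- ranks %*% memb                      # G x K rank sums
  U <- sweep(W, 2, n_k * (n_k + 1) / 2, "-")
  det <- (v > 0) %*% memb                  # in-cluster detections
  det_tot <- rowSums(v > 0)
  lin <- expm1(v)
  S_in <- lin %*% memb
  S_tot <- rowSums(lin)

  out <- vector("list", length(cl))
  for (j in seq_along(cl)) {
    na <- n_k[j]
    nb <- N - na
    mean_in <- S_in[, j] / na
    mean_out <- (S_tot - S_in[, j]) / nb
    lfc <- log(mean_in + 1) - log(mean_out + 1)
    pct_in <- det[, j] / na
    pct_out <- (det_tot - det[, j]) / nb
    if (choose(N, na) <= RANKSUM_MAX_COMB) {
      p <- vapply(seq_len(G), function(g) {
        ranksum_exact_p(ranks[g, ], na, W[g, j])
      }, numeric(1))
    } else {
      sigma2 <- (na * nb / 12) * ((N + 1) - tie_terms / (N * (N - 1)))
      z <- U[, j] - na * nb / 2
      z <- z - sign(z) * 0.5
      p <- ifelse(sigma2 <= 0, 1, pmin(1, 2 * stats::pnorm(-abs(z) / sqrt(pmax(sigma2, 1e-300)))))
    }
    adj <- stats::p.adjust(p, method = "BH")
    tab <- tibble(
      gene = rownames(v), cluster = cl[j],
      log_fold_change = unname(lfc), pct_in = unname(pct_in),
      pct_out = unname(pct_out), p_value = unname(p), adj_p_value = unname(adj)
    )
    tab <- dplyr::filter(
      tab,
      .data$log_fold_change >= min_lfc,
      .data$pct_in >= min_pct_in,
      .data$adj_p_value <= max_adj_p
    )
    tab <- dplyr::arrange(tab, .data$adj_p_value, dplyr::desc(.data$log_fold_change),
                          .data$gene)
    if (!is.null(top_n)) tab <- utils::head(tab, top_n)
    out[[j]] <- tab
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("marker_table", class(res))
  res
}

#' Fiber-type and supporting-cluster marker genes named in the literature
#'
#' A small built-in marker panel for human skeletal muscle: the genes known to
#' separate fast-twitch (type II) from slow-twitch (type I) fiber nuclei, plus
#' endothelial and pericyte-like markers. This is a partial panel of the
#' well-established, text-citable genes, not a full data-driven marker list;
#' for real analyses derive markers from a reference with [find_markers()].
#'
#' @return Named list of character vectors: `type_II` (ATP2A1, MYBPC2, MYH2),
#'   `type_I` (XPO4, ATP2A2, TPM3, MYH7B), `endothelial` (LDB2, VWF, BTNL9,
#'   FLT1, LRRTM4), `pericyte_like` (MECOM).
#' @export
bundled_fiber_markers <- function() {
  list(
    type_II = c("ATP2A1", "MYBPC2", "MYH2"),
    type_I = c("XPO4", "ATP2A2", "TPM3", "MYH7B"),
    endothelial = c("LDB2", "VWF", "BTNL9", "FLT1", "LRRTM4"),
    pericyte_like = "MECOM"
  )
}

## accept a marker_table, any data.frame(gene, cluster), or a named list
normalize_markers <- function(markers) {
  if (is.data.frame(markers)) {
    stopifnot(all(c("gene", "cluster") %in% names(markers)))
    tab <- tibble(gene = as.character(markers$gene),
                  cluster = as.character(markers$cluster))
  } else if (is.list(markers)) {
    tab <- dplyr::bind_rows(imap(markers, function(g, k) tibble(gene = g, cluster = k)))
  } else {
    abort("`markers` must be a data frame with gene/cluster or a named list.")
  }
  dplyr::distinct(tab)
}

#' Build the cluster signature matrix
#'
#' Averages marker-gene expression across the nuclei of each cluster, on the
#' linear CPM scale: the mixing model `x ~ S f` is linear in expression, so
#' signatures are averaged in linear space (never on the log scale). Each
#' nucleus is CPM-normalized over the full gene set first; rows are then
#' restricted to the union of all clusters' marker genes.
#'
#' @param m A [count_matrix()] of counts (UMI or read).
#' @param labels A [cluster_labeling()]; every cluster must be non-empty.
#' @param markers Marker genes: a `marker_table` from [find_markers()], any
#'   data frame with `gene` and `cluster` columns, or a named list of gene
#'   vectors per cluster (e.g. [bundled_fiber_markers()]). Gene ids are
#'   matched after stripping Ensembl version suffixes.
#' @return A [signature_matrix()] (unit CPM) carrying the marker-cluster map.
#' @export
build_signature <- function(m, labels, markers) {
  assert_count_matrix(m, units = c("umi_counts", "read_counts"))
  stopifnot(inherits(labels, "cluster_labeling"))
  assert_labels_match(m, labels)
  mk <- normalize_markers(markers)
  cl <- cluster_ids(labels)
  idx <- match(strip_gene_version(mk$gene), strip_gene_version(gene_ids(m)))
  if (anyNA(idx)) {
    abort(sprintf(
      "marker gene(s) absent from the count matrix: %s",
      paste(unique(mk$gene[is.na(idx)]), collapse = ", ")
    ))
  }
  genes <- unique(gene_ids(m)[idx])
  cpm <- cpm_normalize(m)
  v <- as.matrix(cpm$values[genes, labels$obs_id, drop = FALSE])
  memb <- vapply(cl, function(k) labels$cluster == k, logical(ncol(v)))
  n_k <- colSums(memb)
  if (any(n_k == 0)) abort("empty cluster in the labeling.")
  S <- sweep(v %*% memb, 2, n_k, "/")
  dimnames(S) <- list(genes, cl)
  mk$gene <- gene_ids(m)[idx]
  signature_matrix(S, markers = mk, unit = "cpm")
}
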