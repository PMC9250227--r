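#' Quality-control parameters for single-nuclei references
#'
#' Nuclei with a high fraction of their UMIs coming from mitochondrial or
#' ribosomal genes are typical of damaged or ambient-contaminated droplets and
#' are removed before building signatures. The thresholds default to 0.20:
#' the field's usual "high fraction" cut for snRNA-seq, exposed here because
#' no single value suits every chemistry.
#'
#' Mitochondrial and ribosomal genes are identified by gene-symbol prefix
#' (`MT-`; `RPL`/`RPS`), overridable for other annotations.
#'
#' @param max_mito_fraction,max_ribo_fraction Maximum tolerated fraction of a
#'   nucleus's counts on mitochondrial / ribosomal genes, in `[0, 1]`.
#' @param min_cells_per_gene Keep genes with at least one count in at least
#'   this many retained nuclei (default 1, i.e. drop never-seen genes).
#' @param mito_prefixes,ribo_prefixes Gene-symbol prefixes used to flag the
#'   two gene families.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_mito_fraction = 0.2,
                      max_ribo_fraction = 0.2,
                      min_cells_per_gene = 1L,
                      mito_prefixes = "MT-",
                      ribo_prefixes = c("RPL", "RPS")) {
  stopifnot(
    is.numeric(max_mito_fraction), max_mito_fraction >= 0, max_mito_fraction <= 1,
    is.numeric(max_ribo_fraction), max_ribo_fraction >= 0, max_ribo_fraction <= 1,
    min_cells_per_gene >= 1
  )
  structure(
    list(
      max_mito_fraction = max_mito_fraction,
      max_ribo_fraction = max_ribo_fraction,
      min_cells_per_gene = as.integer(min_cells_per_gene),
      mito_prefixes = mito_prefixes,
      ribo_prefixes = ribo_prefixes
    ),
    class = "qc_params"
  )
}

starts_with_any <- function(x, prefixes) {
  hit <- rep(FALSE, length(x))
  for (p in prefixes) hit <- hit | startsWith(x, p)
  hit
}

#' Filter nuclei and genes of a UMI matrix
#'
#' Two-stage quality control: (1) drop nuclei whose mitochondrial or ribosomal
#' count fraction exceeds its threshold (nuclei with zero total counts are
#' also dropped); (2) among the remaining nuclei, drop genes detected in fewer
#' than `min_cells_per_gene` nuclei. Survivor order is preserved, so the
#' operation is idempotent.
#'
#' @param m A [count_matrix()] of UMI counts.
#' @param params A [qc_params()].
#' @return Filtered [count_matrix()] with attributes `n_nuclei_dropped` and
#'   `n_genes_dropped`.
#' @export
filter_nuclei_and_genes <- function(m, params = qc_params()) {
  assert_count_matrix(m, units = "umi_counts")
  stopifnot(inherits(params, "qc_params"))
  v <- m$values
  totals <- Matrix::colSums(v)
  gmito <- starts_with_any(rownames(v), params$mito_prefixes)
  gribo <- starts_with_any(rownames(v), params$ribo_prefixes)
  mito_frac <- if (any(gmito)) Matrix::colSums(v[gmito, , drop = FALSE]) / totals else rep(0, ncol(v))
  ribo_frac <- if (any(gribo)) Matrix::colSums(v[gribo, , drop = FALSE]) / totals else rep(0, ncol(v))
  keep_nuc <- totals > 0 &
    mito_frac <= params$max_mito_fraction &
    ribo_frac <= params$max_ribo_fraction
  keep_nuc[is.na(keep_nuc)] <- FALSE
  if (!any(keep_nuc)) abort("quality control removed every nucleus.")
  v <- v[, keep_nuc, drop = FALSE]
  det <- Matrix::rowSums(v > 0)
  keep_gene <- det >= params$min_cells_per_gene
  if (!any(keep_gene)) abort("quality control removed every gene.")
  out <- count_matrix(v[keep_gene, , drop = FALSE], m$unit)
  attr(out, "n_nuclei_dropped") <- sum(!keep_nuc)
  attr(out, "n_genes_dropped") <- sum(!keep_gene)
  inform(sprintf(
    "QC: dropped %d/%d nuclei and %d/%d genes.",
    sum(!keep_nuc), length(keep_nuc), sum(!keep_gene), length(keep_gene)
  ))
  out
}
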