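#' Expression matrix with a declared unit
#'
#' A `count_matrix` is the package's shared container for expression data:
#' a genes-by-observations matrix (dense or sparse [Matrix::dgCMatrix-class])
#' together with a unit tag recording what the values mean. Observations are
#' nuclei for single-nuclei references and samples for bulk cohorts.
#'
#' Invariants enforced at construction: no negative or missing entries, and
#' unique, non-empty gene and observation identifiers (the dimnames).
#'
#' @param values Numeric matrix or sparse `Matrix`, genes in rows and
#'   observations in columns, with complete dimnames.
#' @param unit One of `"umi_counts"`, `"read_counts"`, `"cpm"`, `"tpm"`,
#'   `"lognorm"`. Count units are required by the operations that resample or
#'   renormalize (`thin_counts()`, `log_normalize()`, `cpm_normalize()`,
#'   `tmm_factors()`).
#'
#' @return An object of class `count_matrix` with fields `values` and `unit`.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- count_matrix(m, "umi_counts")
#' dim(cm)
#' @export
count_matrix <- function(values,
                         unit = c("umi_counts", "read_counts", "cpm", "tpm", "lognorm")) {
  unit <- match.arg(unit)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    abort("`values` must be a matrix or a Matrix::Matrix.")
  }
  validate_count_values(values)
  structure(list(values = values, unit = unit), class = "count_matrix")
}

validate_count_values <- function(values) {
  gn <- rownames(values)
  on <- colnames(values)
  if (is.null(gn) || is.null(on)) {
    abort("`values` must carry gene ids (rownames) and observation ids (colnames).")
  }
  if (anyDuplicated(gn)) abort("duplicate gene ids are not allowed.")
  if (anyDuplicated(on)) abort("duplicate observation ids are not allowed.")
  mn <- if (methods::is(values, "sparseMatrix")) min(values@x, 0) else min(values)
  if (is.na(mn)) abort("missing values are not allowed in a count matrix.")
  if (mn < 0) abort("negative entries are not allowed in a count matrix.")
  invisible(values)
}

is_count_unit <- function(cm) cm$unit %in% c("umi_counts", "read_counts")

assert_count_matrix <- function(cm, units = NULL, arg = "m") {
  if (!inherits(cm, "count_matrix")) {
    abort(sprintf("`%s` must be a count_matrix (see `count_matrix()`).", arg))
  }
  if (!is.null(units) && !cm$unit %in% units) {
    abort(sprintf(
      "`%s` has unit '%s'; expected one of: %s.",
      arg, cm$unit, paste(units, collapse = ", ")
    ))
  }
  invisible(cm)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.count_matrix <- function(x, ...) as.matrix(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<count_matrix> %d genes x %d observations, unit = %s\n", d[1], d[2], x$unit
  ))
  invisible(x)
}

#' Gene and observation identifiers of a count matrix
#' @param cm A [count_matrix()].
#' @return Character vector of identifiers, in storage order.
#' @export
gene_ids <- function(cm) {
  assert_count_matrix(cm, arg = "cm")
  rownames(cm$values)
}

#' @rdname gene_ids
#' @export
obs_ids <- function(cm) {
  assert_count_matrix(cm, arg = "cm")
  colnames(cm$values)
}

## subset preserving class/unit
cm_subset <- function(cm, genes = NULL, obs = NULL) {
  v <- cm$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(obs)) v <- v[, obs, drop = FALSE]
  count_matrix(v, cm$unit)
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Gene identifiers are matched case-sensitively after removing a trailing
#' `".<digits>"` version suffix (e.g. `ENSG00000000003.14` ->
#' `ENSG00000000003`), since version suffixes break joins between annotation
#' releases while symbols are unaffected.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector with version suffixes removed.
#' @export
strip_gene_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Per-nucleus cluster assignment
#'
#' Builds the cluster labeling used to pair a single-nuclei reference with its
#' clustering (e.g. the five skeletal-muscle clusters: type II fibers, type I
#' fibers, fibroblast-like, endothelial, pericyte-like). Cluster identifiers
#' keep first-appearance order.
#'
#' @param obs_id Character vector of observation (nucleus) identifiers.
#' @param cluster Character vector of cluster identifiers, same length.
#' @return A tibble of class `cluster_labeling` with columns `obs_id` and
#'   `cluster` (a factor whose levels are the cluster ids in first-appearance
#'   order).
#' @export
cluster_labeling <- function(obs_id, cluster) {
  obs_id <- as.character(obs_id)
  cluster <- as.character(cluster)
  if (length(obs_id) != length(cluster)) {
    abort("`obs_id` and `cluster` must have equal length.")
  }
  if (length(obs_id) == 0L) abort("a cluster labeling cannot be empty.")
  dup <- duplicated(obs_id)
  if (any(dup)) {
    ## duplicates allowed only when they repeat the same label
    first <- match(obs_id, obs_id)
    if (any(cluster != cluster[first])) {
      abort("conflicting cluster labels for the same observation.")
    }
    obs_id <- obs_id[!dup]
    cluster <- cluster[!dup]
  }
  lv <- unique(cluster)
  out <- tibble(obs_id = obs_id, cluster = factor(cluster, levels = lv))
  class(out) <- c("cluster_labeling", class(out))
  out
}

#' @rdname cluster_labeling
#' @param labels A `cluster_labeling`.
#' @return `cluster_ids()` returns the ordered cluster identifiers.
#' @export
cluster_ids <- function(labels) levels(labels$cluster)

assert_labels_match <- function(cm, labels) {
  if (!all(labels$obs_id %in% obs_ids(cm))) {
    missing <- setdiff(labels$obs_id, obs_ids(cm))
    abort(sprintf(
      "%d labeled observation(s) absent from the count matrix (e.g. '%s').",
      length(missing), missing[1]
    ))
  }
  invisible(labels)
}

#' Signature matrix of mean marker expression per cluster
#'
#' The reference `S` of the linear mixing model `x ~ S f`: marker genes in
#' rows, clusters in columns, values are mean linear-scale expression (CPM)
#' over the nuclei of each cluster.
#'
#' @param values Dense numeric matrix, marker genes x clusters, non-negative,
#'   with complete dimnames; every row must be positive in at least one
#'   cluster.
#' @param markers Optional tibble with columns `gene` and `cluster` recording
#'   which cluster each marker gene was selected for (used by
#'   `deconvolve_cohort(mode = "fiber_only")` to restrict rows).
#' @param unit Expression unit of the values; `"cpm"` by default.
#' @return An object of class `signature_matrix`.
#' @seealso [build_signature()], [solve_proportions()]
#' @export
signature_matrix <- function(values, markers = NULL, unit = "cpm") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("signature `values` must have gene rownames and cluster colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate signature gene ids.")
  if (anyDuplicated(colnames(values))) abort("duplicate signature cluster ids.")
  if (anyNA(values) || min(values) < 0) {
    abort("signature values must be non-negative and complete.")
  }
  if (any(rowSums(values) <= 0)) {
    abort("every signature gene must be positive in at least one cluster.")
  }
  if (!is.null(markers)) {
    markers <- as_tibble(markers)[, c("gene", "cluster")]
    markers$cluster <- as.character(markers$cluster)
    if (!all(markers$gene %in% rownames(values))) {
      abort("`markers` lists genes absent from the signature rows.")
    }
  }
  structure(list(values = values, markers = markers, unit = unit),
            class = "signature_matrix")
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

#' @export
dimnames.signature_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.signature_matrix <- function(x, ...) x$values

#' @export
print.signature_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<signature_matrix> %d marker genes x %d clusters (%s)\n",
    d[1], d[2], paste(colnames(x$values), collapse = ", ")
  ))
  invisible(x)
}
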