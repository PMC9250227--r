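#' Read an expression matrix from disk
#'
#' Reads either a dense TSV (gene ids in the first column, observation ids in
#' the header) or a MatrixMarket triplet export (`matrix.mtx` plus one-id-per-
#' line or multi-column `genes.tsv` / `barcodes.tsv`, the 10x-style layout).
#' Gzip-compressed variants of every file are accepted. MatrixMarket
#' coordinates are 1-based on disk and converted to the internal order.
#'
#' @param path Path to a dense TSV, or to a `.mtx`(.gz) file, or to a
#'   directory containing `matrix.mtx`, `genes.tsv` and `barcodes.tsv`
#'   (optionally gzipped).
#' @param unit Unit tag to attach; see [count_matrix()].
#' @param genes,barcodes Optional explicit paths to the gene / observation id
#'   files accompanying a `.mtx` file; defaults to `genes.tsv` and
#'   `barcodes.tsv` next to it.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, unit, genes = NULL, barcodes = NULL) {
  if (dir.exists(path)) {
    mtx <- find_sibling(path, "matrix.mtx")
    genes <- genes %||% find_sibling(path, "genes.tsv")
    barcodes <- barcodes %||% find_sibling(path, "barcodes.tsv")
    return(read_mtx_triplet(mtx, genes, barcodes, unit))
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    dirn <- dirname(path)
    genes <- genes %||% find_sibling(dirn, "genes.tsv")
    barcodes <- barcodes %||% find_sibling(dirn, "barcodes.tsv")
    return(read_mtx_triplet(path, genes, barcodes, unit))
  }
  read_dense_tsv(path, unit)
}

find_sibling <- function(dir, name) {
  for (cand in c(file.path(dir, name), file.path(dir, paste0(name, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  abort(sprintf("expected '%s' (or '%s.gz') in %s", name, name, dir))
}

read_id_column <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (nrow(x) == 0L) abort(sprintf("empty id file: %s", path))
  as.character(x[[1]])
}

read_mtx_triplet <- function(mtx, genes, barcodes, unit) {
  for (f in c(mtx, genes, barcodes)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  src <- mtx
  if (grepl("\\.gz$", mtx)) {
    src <- tempfile(fileext = ".mtx")
    on.exit(unlink(src), add = TRUE)
    writeLines(readLines(gzfile(mtx)), src)
  }
  m <- Matrix::readMM(src)
  gid <- read_id_column(genes)
  oid <- read_id_column(barcodes)
  if (nrow(m) != length(gid) || ncol(m) != length(oid)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but ids are %d genes / %d observations.",
      nrow(m), ncol(m), length(gid), length(oid)
    ))
  }
  if (anyDuplicated(gid)) abort("duplicate gene ids in the gene id file.")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(gid, oid)
  count_matrix(m, unit)
}

## read.delim parses doubles with strtod, so values written at %.17g
## round-trip bit-exactly (readr's fast parser can be one ulp off)
read_dense_tsv <- function(path, unit) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  tab <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort("dense TSV needs a gene id column plus >= 1 observation.")
  gid <- as.character(tab[[1]])
  if (anyDuplicated(gid)) abort("duplicate gene ids in dense TSV.")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric entries in dense TSV.")
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(gid, colnames(tab)[-1])
  count_matrix(vals, unit)
}

#' Write an expression matrix to disk
#'
#' Dense TSV output uses genes as rows (the bulk RNA-seq table convention)
#' and writes at full double precision so that a write/read round trip is the
#' identity. MatrixMarket output writes the 10x-style triplet
#' (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`) into a directory.
#'
#' @param cm A [count_matrix()].
#' @param path Output file (TSV) or directory (MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, format = c("tsv", "mtx")) {
  assert_count_matrix(cm, arg = "cm")
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- as_tibble(as.matrix(cm$values))
    tab <- dplyr::bind_cols(tibble(gene = gene_ids(cm)), tab)
    write_tsv_full(tab, path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sp <- methods::as(methods::as(cm$values, "dMatrix"), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(cm), file.path(path, "genes.tsv"))
    writeLines(obs_ids(cm), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read per-nucleus cluster labels
#'
#' Expects a two-column TSV `(observation_id, cluster_id)`. A header row is
#' optional and detected by its first field (`obs_id`, `barcode`, `cell`,
#' `nucleus` or `observation`, case-insensitive). Duplicate rows repeating the
#' same label are collapsed; conflicting labels are an error.
#'
#' @param path Path to the TSV (gzip accepted).
#' @return A [cluster_labeling()] with cluster ids in first-appearance order.
#' @export
read_cluster_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (nrow(tab) == 0L) abort("empty cluster label file.")
  if (ncol(tab) < 2L) abort("cluster label file needs two columns.")
  if (tolower(tab[[1]][1]) %in% c("obs_id", "barcode", "cell", "nucleus", "observation")) {
    tab <- tab[-1, , drop = FALSE]
    if (nrow(tab) == 0L) abort("cluster label file has a header but no rows.")
  }
  cluster_labeling(tab[[1]], tab[[2]])
}

#' Read a measured fiber-fraction table
#'
#' Two-column TSV `(sample_id, type1_fraction)` with fractions in `[0, 1]`,
#' e.g. ATPase staining or MyHC isoform measurements used as validation truth.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `sample_id`, `type1_fraction`.
#' @export
read_fiber_fractions <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  tab <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort("fiber fraction table needs two columns.")
  out <- tibble(sample_id = as.character(tab[[1]]),
                type1_fraction = as.numeric(tab[[2]]))
  if (anyNA(out$type1_fraction) ||
      any(out$type1_fraction < 0 | out$type1_fraction > 1)) {
    abort("fiber fractions must be numbers in [0, 1].")
  }
  out
}

#' Write a result table or signature to TSV
#'
#' TSVs are written with a stable column order and full float precision, so
#' that reading the file back reproduces the values exactly.
#'
#' @param obj A [signature_matrix()] or a data frame (marker table, proportion
#'   estimates, downsample curve, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.signature_matrix <- function(obj, path) {
  tab <- dplyr::bind_cols(tibble(gene = rownames(obj$values)),
                          as_tibble(obj$values))
  write_tsv_full(tab, path)
  invisible(path)
}

#' @export
write_table.data.frame <- function(obj, path) {
  drop <- vapply(obj, is.list, logical(1))
  write_tsv_full(as_tibble(obj)[, !drop, drop = FALSE], path)
  invisible(path)
}

## %.17g guarantees that doubles survive a write/read round trip exactly
write_tsv_full <- function(tab, path) {
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_tsv(tab, path, progress = FALSE)
}

#' Read a signature matrix written by [write_table()]
#' @param path Path to the signature TSV (gene column + one column per cluster).
#' @param unit Expression unit of the stored values.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path, unit = "cpm") {
  cm <- read_dense_tsv(path, "cpm")
  signature_matrix(as.matrix(cm$values), unit = unit)
}
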