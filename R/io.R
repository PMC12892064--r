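#' Read / write single-cell matrices in standard plain-text formats
#'
#' RNA counts use the 10x-style triplet layout: `matrix.mtx` (Matrix Market,
#' features x barcodes), `features.tsv` and `barcodes.tsv`. Protein matrices
#' are TSV with proteins in rows and cells in columns; empty/NA entries are
#' the explicit missing mask. Annotations are plain TSV keyed by `cell_id`.
#'
#' @param x an `scm` object.
#' @param dir directory for the MTX triplet.
#' @return readers return an `scm`; writers return the path(s) invisibly.
#' @export
write_rna_mtx <- function(x, dir) {
  stopifnot(inherits(x, "scm"), x$modality == "rna")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(scm_values(x)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(feature_id = feature_ids(x),
                                  name = feature_ids(x)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = cell_ids(x)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' @rdname write_rna_mtx
#' @export
read_rna_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), col_names = FALSE,
                           show_col_types = FALSE)
  bcs <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = FALSE,
                         show_col_types = FALSE)
  v <- t(as.matrix(m))
  dimnames(v) <- list(bcs[[1]], feats[[1]])
  scm(v, "rna")
}

#' @rdname write_rna_mtx
#' @param path TSV file path (protein matrix: rows = proteins, columns =
#'   cells).
#' @export
write_protein_tsv <- function(x, path) {
  stopifnot(inherits(x, "scm"), x$modality == "protein")
  d <- as.data.frame(t(scm_values(x)))
  d <- cbind(protein = feature_ids(x), d)
  readr::write_tsv(tibble::as_tibble(d), path)
  invisible(path)
}

#' @rdname write_rna_mtx
#' @export
read_protein_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  feats <- d[[1]]
  v <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(v) <- feats
  scm(v, "protein")
}
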