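#' Single-cell expression matrix container
#'
#' A light wrapper around a dense cells-by-features matrix carrying the
#' modality (`"rna"` or `"protein"`), and the transform state of the values.
#' Missing protein measurements are encoded as `NA` — an explicit mask, never
#' zeros — so that detection-biased missingness can be analysed and imputed
#' honestly. RNA matrices must be complete (counts; zeros are true zeros).
#'
#' Transform states only advance `raw` -> `normalized_log1p` -> `imputed`.
#'
#' @param values numeric matrix, cells in rows, features in columns, with
#'   unique row and column names (cell ids / feature ids). Non-negative;
#'   `NA` entries allowed for protein only.
#' @param modality `"rna"` or `"protein"`.
#' @param transform one of `"raw"`, `"normalized_log1p"`, `"imputed"`.
#' @return an object of class `scm`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' x <- scm(m, "rna")
#' n_cells(x)
#' @export
scm <- function(values, modality = c("rna", "protein"),
                transform = c("raw", "normalized_log1p", "imputed")) {
  modality <- match.arg(modality)
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x features)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have cell ids as rownames and feature ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("cell ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("feature ids must be unique", call. = FALSE)
  if (any(values < 0, na.rm = TRUE) && transform == "raw") {
    stop("raw values must be non-negative", call. = FALSE)
  }
  if (modality == "rna" && anyNA(values)) {
    stop("RNA matrices carry no missing mask; NA entries are not allowed",
         call. = FALSE)
  }
  structure(list(values = values, modality = modality, transform = transform),
            class = "scm")
}

#' @export
print.scm <- function(x, ...) {
  miss <- if (anyNA(x$values)) {
    sprintf(", %.1f%% missing", 100 * mean(is.na(x$values)))
  } else ""
  cat(sprintf("<scm> %s [%s]: %d cells x %d features%s\n",
              x$modality, x$transform, nrow(x$values), ncol(x$values), miss))
  invisible(x)
}

#' Accessors for `scm` objects
#' @param x an `scm` object.
#' @return `scm_values()` the numeric matrix; `cell_ids()` / `feature_ids()`
#'   character vectors; `n_cells()` / `n_features()` integers;
#'   `missing_mask()` a logical matrix (`TRUE` where unobserved).
#' @export
scm_values <- function(x) x$values

#' @rdname scm_values
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname scm_values
#' @export
feature_ids <- function(x) colnames(x$values)

#' @rdname scm_values
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname scm_values
#' @export
n_features <- function(x) ncol(x$values)

#' @rdname scm_values
#' @export
missing_mask <- function(x) is.na(x$values)

# internal: advance transform state, erroring on regressions
advance_transform <- function(x, to) {
  order <- c(raw = 1L, normalized_log1p = 2L, imputed = 3L)
  if (order[[to]] <= order[[x$transform]] && !(to == x$transform)) {
    stop(sprintf("cannot move transform state backwards (%s -> %s)",
                 x$transform, to), call. = FALSE)
  }
  x$transform <- to
  x
}

# internal: subset an scm keeping class/metadata
scm_subset <- function(x, cells = NULL, features = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  out <- x
  out$values <- v
  out
}

#' Per-cell annotation table derived from a matrix
#'
#' Computes the per-cell QC statistics used by the filtering gates:
#' `total_counts` (RNA), `n_features_detected` (non-zero for RNA, non-missing
#' for protein) and `log2_sum_sn` (protein; log2 of the summed reporter S/N
#' across all observed proteins). Joined onto an existing annotation table if
#' one is supplied.
#'
#' @param x an `scm` object (raw values for meaningful QC statistics).
#' @param ann optional existing annotation tibble with a `cell_id` column
#'   (e.g. time points, FUCCI intensities); QC columns are added/refreshed.
#' @return a tibble with one row per cell.
#' @export
annotate_cells <- function(x, ann = NULL) {
  v <- scm_values(x)
  qc <- tibble::tibble(cell_id = rownames(v))
  if (x$modality == "rna") {
    qc$total_counts <- as.integer(round(rowSums(v)))
    qc$n_features_detected <- as.integer(rowSums(v > 0))
  } else {
    sums <- rowSums(v, na.rm = TRUE)
    qc$log2_sum_sn <- ifelse(sums > 0, log2(sums), NA_real_)
    qc$n_features_detected <- as.integer(rowSums(!is.na(v)))
  }
  if (!is.null(ann)) {
    stopifnot("cell_id" %in% names(ann))
    keep <- setdiff(names(ann), setdiff(names(qc), "cell_id"))
    qc <- dplyr::left_join(qc, ann[keep], by = "cell_id")
  }
  qc
}

# internal: check annotations align with matrix cells
check_alignment <- function(x, ann) {
  if (!identical(sort(ann$cell_id), sort(cell_ids(x))) ||
      nrow(ann) != n_cells(x)) {
    stop("annotation table does not align with matrix cells", call. = FALSE)
  }
  ann[match(cell_ids(x), ann$cell_id), , drop = FALSE]
}
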