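#' Diffusion map of a marker-restricted expression matrix
#'
#' Builds a Euclidean k-NN graph (per-feature z-scored data), applies a
#' Gaussian kernel with per-cell adaptive bandwidth (distance to the
#' `ceiling(k/2)`-th neighbor), symmetrizes by the mean, applies the
#' anisotropic density correction (alpha = 1: kernel divided by the product
#' of row sums), row-normalizes to a transition matrix and eigendecomposes
#' through the symmetric conjugate, so eigenvalues are real and the top
#' eigenvalue is exactly 1 (stationary component). Missing entries (protein
#' before imputation) are handled through mutual-feature distances.
#'
#' @param x an `scm` (normalized or imputed).
#' @param markers optional [marker_set()] / character vector restricting the
#'   features used.
#' @param n_neighbors k of the k-NN graph.
#' @param n_comps number of eigencomponents to keep (`< n_cells`).
#' @param scale_features z-score each feature before distances (default).
#' @return a `diffusion_result`: eigenvalues `evals` (decreasing, first = 1),
#'   symmetric-convention eigenvectors `evecs` (orthonormal), right
#'   eigenvectors `psi` (orthonormal under the stationary measure),
#'   `stationary` weights, `cell_ids`.
#' @export
diffusion_map <- function(x, markers = NULL, n_neighbors = 15L, n_comps = 10L,
                          scale_features = TRUE) {
  stopifnot(inherits(x, "scm"))
  v <- scm_values(x)
  if (!is.null(markers)) {
    keep <- intersect(as.character(markers), colnames(v))
    if (!length(keep)) stop("no marker features present in the matrix", call. = FALSE)
    v <- v[, keep, drop = FALSE]
  }
  n <- nrow(v)
  if (n < n_neighbors + 1L) stop("need at least n_neighbors + 1 cells", call. = FALSE)
  if (n_comps >= n) stop("n_comps must be smaller than the number of cells", call. = FALSE)
  if (scale_features) {
    mu <- colMeans(v, na.rm = TRUE)
    sd <- apply(v, 2, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- 1
    v <- sweep(sweep(v, 2, mu), 2, sd, `/`)
  }
  d2 <- if (anyNA(v)) {
    # overlap guard adapts to the (possibly marker-restricted) panel size
    masked_dist2(v, min_overlap = min(20L, max(3L, ceiling(0.1 * ncol(v)))))
  } else {
    as.matrix(stats::dist(v))^2
  }
  # adaptive bandwidth: distance to the ceiling(k/2)-th neighbor
  kband <- ceiling(n_neighbors / 2)
  ord <- apply(d2, 1, order)
  sigma <- vapply(seq_len(n), function(i) sqrt(d2[i, ord[kband + 1L, i]]), numeric(1))
  sigma[sigma <= 0 | !is.finite(sigma)] <- 1e-12
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- ord[2:(n_neighbors + 1L), i]
    nb <- nb[is.finite(d2[i, nb])]
    w[i, nb] <- exp(-d2[i, nb] / (sigma[i] * sigma[nb]))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    w > 0, mode = "undirected"))
  if (comp$no > 1) {
    stop("neighbor graph is disconnected (component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "), ")",
         call. = FALSE)
  }
  q <- rowSums(w)
  w <- w / outer(q, q)                     # alpha = 1 density correction
  d <- rowSums(w)
  s <- w / outer(sqrt(d), sqrt(d))         # symmetric conjugate of T = D^-1 W
  es <- eigen(s, symmetric = TRUE)
  idx <- seq_len(n_comps)
  evals <- es$values[idx]
  evecs <- es$vectors[, idx, drop = FALSE]
  # fix eigenvector signs deterministically (largest-|entry| positive)
  for (j in seq_len(ncol(evecs))) {
    piv <- which.max(abs(evecs[, j]))
    if (evecs[piv, j] < 0) evecs[, j] <- -evecs[, j]
  }
  psi <- evecs / sqrt(d)
  structure(list(evals = evals, evecs = evecs, psi = psi,
                 stationary = d / sum(d), cell_ids = rownames(v),
                 n_neighbors = n_neighbors),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> %d cells, %d components; lambda_2 = %.4f\n",
              length(x$cell_ids), length(x$evals),
              if (length(x$evals) > 1) x$evals[2] else NA_real_))
  invisible(x)
}

#' Diffusion pseudotime from a root cell
#'
#' `dpt(x, root)^2 = sum_{i >= 2} (lambda_i / (1 - lambda_i))^2
#' (psi_i(x) - psi_i(root))^2`: the Euclidean distance between accumulated
#' random-walk transition profiles, computed spectrally from the diffusion
#' components (symmetric-operator convention).
#'
#' @param diff a [diffusion_map()] result with at least 2 components.
#' @param root cell id of the root.
#' @return a `pseudotime_result`: `root`, `dpt` (named, 0 at root),
#'   `cell_ids`; orientation and ranks are added by
#'   [pseudotemporal_order()].
#' @export
dpt_pseudotime <- function(diff, root) {
  stopifnot(inherits(diff, "diffusion_result"))
  if (length(diff$evals) < 2) stop("need at least 2 components", call. = FALSE)
  ri <- match(root, diff$cell_ids)
  if (is.na(ri)) stop("root cell not found", call. = FALSE)
  lam <- diff$evals[-1]
  if (any(lam >= 1 - 1e-10)) {
    stop("non-stationary eigenvalue equal to 1: graph is disconnected", call. = FALSE)
  }
  vv <- diff$evecs[, -1, drop = FALSE]
  wgt <- lam / (1 - lam)
  delta <- sweep(vv, 2, vv[ri, ])
  dpt <- sqrt(rowSums(sweep(delta, 2, wgt, `*`)^2))
  dpt[ri] <- 0
  names(dpt) <- diff$cell_ids
  structure(list(root = root, dpt = dpt, cell_ids = diff$cell_ids,
                 oriented = FALSE),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("<pseudotime_result> %d cells, root %s%s\n", length(x$dpt),
              x$root, if (isTRUE(x$oriented)) ", oriented" else ""))
  invisible(x)
}

#' Oriented pseudotemporal order
#'
#' Flips the pseudotime axis when its Spearman correlation with real sampling
#' time is negative, assigns ranks by ascending oriented pseudotime (ties
#' broken by cell id) and summarizes normalized pseudotime (dpt / max) per
#' time point (median, IQR).
#'
#' @param pt a [dpt_pseudotime()] result.
#' @param ann annotation tibble with `cell_id` and `time_point_h`.
#' @return the `pseudotime_result` with `oriented_dpt`, `u` (normalized),
#'   `order` (0-based ranks), `orientation` (+1/-1), `spearman_time` and
#'   `summary` (tibble: time_point_h, median_u, iqr_u, n).
#' @export
pseudotemporal_order <- function(pt, ann) {
  stopifnot(inherits(pt, "pseudotime_result"))
  tp <- ann$time_point_h[match(pt$cell_ids, ann$cell_id)]
  rho <- suppressWarnings(stats::cor(pt$dpt, tp, method = "spearman"))
  orientation <- if (!is.na(rho) && rho < 0) -1 else 1
  od <- if (orientation < 0) max(pt$dpt) - pt$dpt else pt$dpt
  ord <- order(od, pt$cell_ids)
  ranks <- integer(length(od))
  ranks[ord] <- seq_along(od) - 1L
  u <- if (max(od) > 0) od / max(od) else od
  pt$oriented_dpt <- od
  pt$u <- u
  pt$order <- stats::setNames(ranks, pt$cell_ids)
  pt$orientation <- orientation
  pt$oriented <- TRUE
  pt$spearman_time <- suppressWarnings(stats::cor(od, tp, method = "spearman"))
  pt$time_point_h <- stats::setNames(tp, pt$cell_ids)
  pt$summary <- tibble::tibble(time_point_h = tp, u = u) |>
    dplyr::group_by(.data$time_point_h) |>
    dplyr::summarise(median_u = stats::median(.data$u),
                     iqr_u = stats::IQR(.data$u), n = dplyr::n())
  pt
}

#' Root-cell selection for the hypoxia trajectory
#'
#' The root is the time-0 cell with the lowest mean z-scored expression of
#' the upregulated stimulus markers (direction from each marker's correlation
#' with sampling time); if no time-0 cells exist, the global minimum is used
#' (recorded in the `fallback` attribute). With a degenerate (constant)
#' matrix the first cell id in lexicographic order is returned.
#'
#' @param x the `scm` used for the trajectory.
#' @param markers [marker_set()] or character vector (non-empty).
#' @param ann annotation tibble with `cell_id`, `time_point_h`.
#' @return root cell id (character); attribute `fallback` TRUE when no
#'   time-0 cells were available.
#' @export
choose_root <- function(x, markers, ann) {
  if (!length(markers)) stop("empty marker set", call. = FALSE)
  v <- scm_values(x)[, intersect(as.character(markers), feature_ids(x)), drop = FALSE]
  if (!ncol(v)) stop("no marker features present", call. = FALSE)
  tp <- ann$time_point_h[match(rownames(v), ann$cell_id)]
  sds <- apply(v, 2, stats::sd)
  if (all(sds == 0)) {
    root <- sort(rownames(v))[1]
    attr(root, "fallback") <- FALSE
    return(root)
  }
  z <- sweep(sweep(v, 2, colMeans(v)), 2, pmax(sds, 1e-12), `/`)
  dir <- sign(suppressWarnings(as.vector(stats::cor(tp, v))))
  dir[is.na(dir) | dir == 0] <- 1
  score <- rowMeans(sweep(z, 2, dir, `*`))
  cand <- which(tp == 0)
  fallback <- FALSE
  if (!length(cand)) {
    cand <- seq_along(score)
    fallback <- TRUE
  }
  root <- rownames(v)[cand[which.min(score[cand])]]
  attr(root, "fallback") <- fallback
  root
}
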