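#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pseudotime result
#'
#' @param x a `pseudotime_result`.
#' @param ... unused.
#' @return tibble: cell_id, dpt, and (after [pseudotemporal_order()])
#'   oriented_dpt, u, rank, time_point_h.
#' @method tidy pseudotime_result
#' @export
tidy.pseudotime_result <- function(x, ...) {
  out <- tibble::tibble(cell_id = x$cell_ids, dpt = unname(x$dpt))
  if (isTRUE(x$oriented)) {
    out$oriented_dpt <- unname(x$oriented_dpt)
    out$u <- unname(x$u)
    out$rank <- unname(x$order)
    out$time_point_h <- unname(x$time_point_h)
  }
  out
}

#' @rdname tidy.pseudotime_result
#' @method glance pseudotime_result
#' @export
glance.pseudotime_result <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$dpt), root = x$root,
    oriented = isTRUE(x$oriented),
    spearman_time = if (isTRUE(x$oriented)) x$spearman_time else NA_real_
  )
}

#' Tidy a diffusion-map spectrum
#'
#' @param x a `diffusion_result`.
#' @param ... unused.
#' @return tibble: component, eigenvalue.
#' @method tidy diffusion_result
#' @export
tidy.diffusion_result <- function(x, ...) {
  tibble::tibble(component = seq_along(x$evals), eigenvalue = x$evals)
}

#' @rdname tidy.diffusion_result
#' @method glance diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble::tibble(n_cells = length(x$cell_ids), n_comps = length(x$evals),
                 lambda_2 = if (length(x$evals) > 1) x$evals[2] else NA_real_,
                 spectral_gap = if (length(x$evals) > 2)
                   x$evals[2] - x$evals[3] else NA_real_)
}

#' Tidy an axis alignment
#'
#' @param x an `alignment_warp`.
#' @param ... unused.
#' @return the per-cell common-axis coordinates tibble.
#' @method tidy alignment_warp
#' @export
tidy.alignment_warp <- function(x, ...) x$coords

#' @rdname tidy.alignment_warp
#' @method glance alignment_warp
#' @export
glance.alignment_warp <- function(x, ...) {
  tibble::tibble(n_anchors = nrow(x$anchors), identity = x$identity,
                 max_warp_shift = max(abs(x$warp(x$anchors$u_prot) -
                                            x$anchors$u_prot)))
}
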