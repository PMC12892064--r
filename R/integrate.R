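# piecewise-linear monotone warp through anchor pairs, endpoints pinned at
# (0,0)/(1,1), anchors repaired by pool-adjacent-violators
build_warp <- function(u_from, u_to) {
  ax <- c(0, u_from, 1)
  ay <- c(0, u_to, 1)
  o <- order(ax)
  ax <- ax[o]; ay <- ay[o]
  ay <- stats::isoreg(ax, ay)$yf
  ay[1] <- 0; ay[length(ay)] <- 1
  keep <- !duplicated(ax)
  ax <- ax[keep]; ay <- ay[keep]
  # all interior anchors collapsed onto one point: fall back to identity
  degenerate <- length(unique(u_from)) == 1 && length(unique(u_to)) == 1 &&
    length(u_from) > 1
  if (degenerate) {
    return(list(warp = function(u) u, identity = TRUE, degenerate = TRUE))
  }
  warp <- function(u) stats::approx(ax, ay, xout = u, rule = 2,
                                    ties = "ordered")$y
  list(warp = warp, identity = all(abs(ay - ax) < 1e-12), degenerate = FALSE)
}

#' Align two pseudotemporal axes through shared time-point anchors
#'
#' Each modality's cells get a normalized order coordinate `u = rank/(n-1)`.
#' For every shared sampling time the pair (median protein u, median RNA u)
#' becomes an anchor; anchors are repaired to monotonicity by
#' pool-adjacent-violators, endpoints are pinned at (0,0) and (1,1), and the
#' piecewise-linear warp maps the protein axis onto the RNA axis (the RNA
#' axis is the common axis: it carries more cells and a finer order).
#'
#' @param pt_rna,pt_prot oriented [pseudotemporal_order()] results.
#' @param ann_rna,ann_prot annotation tibbles with `cell_id`,
#'   `time_point_h`.
#' @return an `alignment_warp`: `anchors` (tibble), `warp` (function),
#'   `coords` (tibble: cell_id, modality, u, common_u).
#' @export
align_axes <- function(pt_rna, pt_prot, ann_rna, ann_prot) {
  stopifnot(isTRUE(pt_rna$oriented), isTRUE(pt_prot$oriented))
  u_of <- function(pt) pt$order / max(1L, length(pt$order) - 1L)
  u_rna <- u_of(pt_rna)
  u_prot <- u_of(pt_prot)
  tp_rna <- ann_rna$time_point_h[match(pt_rna$cell_ids, ann_rna$cell_id)]
  tp_prot <- ann_prot$time_point_h[match(pt_prot$cell_ids, ann_prot$cell_id)]
  shared <- sort(intersect(unique(tp_rna), unique(tp_prot)))
  if (length(shared) < 2) stop("need at least 2 shared time points", call. = FALSE)
  anchors <- tibble::tibble(
    time_point_h = shared,
    u_prot = vapply(shared, function(t) stats::median(u_prot[tp_prot == t]), numeric(1)),
    u_rna = vapply(shared, function(t) stats::median(u_rna[tp_rna == t]), numeric(1))
  )
  wb <- build_warp(anchors$u_prot, anchors$u_rna)
  warp <- wb$warp
  identity_warp <- wb$identity
  if (wb$degenerate) warning("all anchors identical; using identity warp")
  coords <- dplyr::bind_rows(
    tibble::tibble(cell_id = pt_rna$cell_ids, modality = "rna",
                   u = unname(u_rna), common_u = unname(u_rna)),
    tibble::tibble(cell_id = pt_prot$cell_ids, modality = "protein",
                   u = unname(u_prot), common_u = warp(unname(u_prot)))
  )
  structure(list(anchors = anchors, warp = warp, coords = coords,
                 identity = identity_warp),
            class = "alignment_warp")
}

#' @export
print.alignment_warp <- function(x, ...) {
  cat(sprintf("<alignment_warp> %d anchors%s; %d cells on the common axis\n",
              nrow(x$anchors), if (x$identity) " (identity)" else "",
              nrow(x$coords)))
  invisible(x)
}

#' Standardized feature profiles along the common axis
#'
#' Each feature is z-scored across the cells of its modality; at every grid
#' point on the common axis the windowed mean of the z-scores is taken over
#' cells inside the centered window, with a 95% t-interval. Windows holding
#' fewer than `min_cells` cells are masked. Zero-variance features yield a
#' profile of zeros with `degenerate = TRUE`.
#'
#' @param x normalized (protein: imputed) `scm`.
#' @param coords coords tibble from [align_axes()] (or any tibble with
#'   `cell_id`, `common_u`).
#' @param features feature ids to profile.
#' @param window_fraction window width as a fraction of the axis, in
#'   `(0, 0.5]`.
#' @param grid_size number of grid points on `[0, 1]`.
#' @param min_cells minimum cells per window.
#' @return tibble of class `joint_profile`: feature, modality, u, mean, lo,
#'   hi, n, degenerate.
#' @export
feature_profile <- function(x, coords, features, window_fraction = 0.1,
                            grid_size = 100L, min_cells = 5L) {
  stopifnot(inherits(x, "scm"), window_fraction > 0, window_fraction <= 0.5)
  v <- scm_values(x)
  features <- intersect(features, colnames(v))
  if (!length(features)) stop("no requested features in the matrix", call. = FALSE)
  cu <- coords$common_u[match(rownames(v), coords$cell_id)]
  ok <- !is.na(cu)
  v <- v[ok, , drop = FALSE]
  cu <- cu[ok]
  grid <- seq(0, 1, length.out = grid_size)
  half <- window_fraction / 2
  out <- purrr::map_dfr(features, function(f) {
    y <- v[, f]
    obs <- !is.na(y)
    s <- stats::sd(y[obs])
    degenerate <- !is.finite(s) || s == 0
    z <- if (degenerate) rep(0, length(y)) else (y - mean(y[obs])) / s
    res <- vapply(grid, function(g) {
      inw <- obs & cu >= g - half & cu <= g + half
      nw <- sum(inw)
      if (nw < min_cells) return(c(NA_real_, NA_real_, NA_real_, nw))
      m <- mean(z[inw])
      se <- stats::sd(z[inw]) / sqrt(nw)
      tq <- stats::qt(0.975, nw - 1)
      c(m, m - tq * se, m + tq * se, nw)
    }, numeric(4))
    tibble::tibble(feature = f, modality = x$modality, u = grid,
                   mean = res[1, ], lo = res[2, ], hi = res[3, ],
                   n = as.integer(res[4, ]), degenerate = degenerate)
  })
  class(out) <- c("joint_profile", class(out))
  out
}

#' Response onset and transcription-translation lag
#'
#' Per modality, the onset is the earliest real time at which the per-time-
#' point median normalized pseudotime completes `threshold` of its rise from
#' the baseline (time 0) value to its final value, linearly interpolated
#' between sampled times — the same baseline-relative half-response
#' convention as a first-order kinetic lag. The rule is a ratio, so it is
#' invariant to shifting or rescaling the pseudotime axis. The lag is
#' protein onset minus RNA onset.
#'
#' @param summary_rna,summary_prot tibbles with `time_point_h` and
#'   `median_u` (from [pseudotemporal_order()]`$summary`), covering at least
#'   3 time points including time 0.
#' @param threshold fraction of the final value (default 0.5).
#' @return an `onset_lag` tibble row: onset_rna_h, onset_prot_h, lag_h,
#'   threshold; undefined onsets are `NA` and flagged in the `undefined`
#'   attribute.
#' @export
estimate_onset_lag <- function(summary_rna, summary_prot, threshold = 0.5) {
  onset_of <- function(sm) {
    sm <- dplyr::arrange(sm, .data$time_point_h)
    if (nrow(sm) < 3 || sm$time_point_h[1] != 0) {
      stop("summaries must cover >= 3 time points including time 0", call. = FALSE)
    }
    f <- sm$median_u
    t <- sm$time_point_h
    rise <- f[length(f)] - f[1]
    if (rise <= 1e-12) return(NA_real_)   # flat or inverted: onset undefined
    target <- f[1] + threshold * rise
    above <- which(f >= target)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1) return(t[1])
    # linear interpolation between the straddling samples
    t[i - 1] + (target - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
  }
  on_r <- onset_of(summary_rna)
  on_p <- onset_of(summary_prot)
  out <- tibble::tibble(onset_rna_h = on_r, onset_prot_h = on_p,
                        lag_h = on_p - on_r, threshold = threshold)
  class(out) <- c("onset_lag", class(out))
  attr(out, "undefined") <- c(rna = is.na(on_r), protein = is.na(on_p))
  out
}

#' Demarcate prehypoxia and established-response zones
#'
#' The end of the prehypoxia zone (`u_pre`) is the first grid point at which
#' the mean profile of the fast anchor markers exceeds `z_threshold` and
#' stays above it for at least `persistence` consecutive grid points; the
#' start of the established zone (`u_onset`) applies the same rule to the
#' slow anchor markers.
#'
#' @param profiles a [feature_profile()] tibble on the common axis.
#' @param fast_markers,slow_markers feature ids of sharp (BNIP3/NDRG1-like)
#'   and slow (VEGFA-like) anchors.
#' @param z_threshold standardized-abundance crossing level.
#' @param persistence consecutive grid points required above threshold.
#' @return a `zones` list: `u_pre`, `u_onset` (NA and flagged when no
#'   sustained crossing exists), marker ids used.
#' @export
demarcate_zones <- function(profiles, fast_markers, slow_markers,
                            z_threshold = 0.5, persistence = 3L) {
  crossing <- function(ids) {
    pr <- profiles |>
      dplyr::filter(.data$feature %in% ids) |>
      dplyr::group_by(.data$u) |>
      dplyr::summarise(m = mean(.data$mean, na.rm = TRUE)) |>
      dplyr::arrange(.data$u)
    above <- !is.na(pr$m) & pr$m > z_threshold
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    hit <- which(run$values & run$lengths >= persistence)
    if (!length(hit)) return(NA_real_)
    pr$u[starts[hit[1]]]
  }
  u_pre <- crossing(fast_markers)
  u_onset <- crossing(slow_markers)
  structure(list(u_pre = u_pre, u_onset = u_onset,
                 fast_markers = fast_markers, slow_markers = slow_markers,
                 z_threshold = z_threshold, persistence = persistence,
                 undefined = c(pre = is.na(u_pre), onset = is.na(u_onset))),
            class = "zones")
}

#' @export
print.zones <- function(x, ...) {
  cat(sprintf("<zones> prehypoxia ends at u = %s; established response from u = %s\n",
              format(x$u_pre, digits = 3), format(x$u_onset, digits = 3)))
  invisible(x)
}
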