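# build an oriented pseudotime_result directly from known ranks (fixture)
fake_pt <- function(u, time, prefix = "c") {
  ids <- sprintf("%s%03d", prefix, seq_along(u))
  ord <- integer(length(u)); ord[order(u, ids)] <- seq_along(u) - 1L
  structure(list(root = ids[which.min(u)], dpt = stats::setNames(u, ids),
                 cell_ids = ids, oriented = TRUE,
                 oriented_dpt = stats::setNames(u, ids),
                 u = u / max(u), order = stats::setNames(ord, ids),
                 orientation = 1, spearman_time = 1,
                 time_point_h = stats::setNames(time, ids)),
            class = "pseudotime_result")
}

test_that("anchor warp interpolates piecewise-linearly and stays monotone", {
  w <- pseudolign:::build_warp(c(0.2, 0.6), c(0.3, 0.7))
  expect_equal(w$warp(0.4), 0.5)                  # between the two anchors
  expect_equal(w$warp(c(0, 0.2, 0.6, 1)), c(0, 0.3, 0.7, 1))
  expect_false(w$identity)
  # identity when anchors already match
  wi <- pseudolign:::build_warp(c(0.25, 0.5), c(0.25, 0.5))
  expect_true(wi$identity)
  expect_equal(wi$warp(0.37), 0.37)
  # monotone after isotonic repair, for random (possibly inverted) anchors
  set.seed(4)
  for (i in 1:50) {
    ww <- pseudolign:::build_warp(sort(runif(5)), runif(5))
    u <- sort(runif(40))
    expect_true(all(diff(ww$warp(u)) >= -1e-12))
  }
})

test_that("axis alignment warps protein onto the RNA axis via shared anchors", {
  n <- 60
  t_r <- rep(c(0, 2, 4, 8), length.out = n)
  t_p <- rep(c(0, 2, 4, 6, 8), length.out = n)
  pt_r <- fake_pt(rank(t_r + seq_len(n) * 1e-3), t_r, "r")
  pt_p <- fake_pt(rank(t_p + seq_len(n) * 1e-3), t_p, "p")
  ann_r <- tibble::tibble(cell_id = pt_r$cell_ids, time_point_h = t_r)
  ann_p <- tibble::tibble(cell_id = pt_p$cell_ids, time_point_h = t_p)
  al <- align_axes(pt_r, pt_p, ann_r, ann_p)
  expect_s3_class(al, "alignment_warp")
  expect_equal(nrow(al$anchors), 4)               # shared times 0,2,4,8
  expect_true(all(diff(al$anchors$u_prot) > 0))
  expect_true(all(diff(al$anchors$u_rna) > 0))
  co <- al$coords
  expect_setequal(co$modality, c("rna", "protein"))
  expect_true(all(co$common_u >= 0 & co$common_u <= 1))
  # warping preserves the within-modality cell order exactly
  pr <- co[co$modality == "protein", ]
  expect_identical(order(pr$common_u, pr$cell_id), order(pr$u, pr$cell_id))
  # common-axis coordinates invariant to cell relabeling
  pt_p2 <- pt_p
  relab <- sub("^p", "q", pt_p2$cell_ids)
  names(pt_p2$dpt) <- names(pt_p2$oriented_dpt) <- names(pt_p2$order) <-
    names(pt_p2$time_point_h) <- relab
  pt_p2$cell_ids <- relab
  pt_p2$root <- sub("^p", "q", pt_p2$root)
  ann_p2 <- dplyr::mutate(ann_p, cell_id = relab)
  al2 <- align_axes(pt_r, pt_p2, ann_r, ann_p2)
  expect_equal(al2$coords$common_u, al$coords$common_u)
  # fewer than 2 shared time points errors
  ann_p3 <- dplyr::mutate(ann_p, time_point_h = time_point_h + 0.1)
  expect_error(align_axes(pt_r, pt_p, ann_r, ann_p3), "shared time points")
})

test_that("feature profiles are windowed standardized means with t-bands", {
  set.seed(7)
  n <- 400
  u <- runif(n)
  v <- cbind(lin = 2 + 3 * u, const = rep(5, n),
             noisy = 1 + u + rnorm(n, 0, 0.1))
  rownames(v) <- sprintf("c%03d", seq_len(n))
  x <- mk_scm(v, "rna", "normalized_log1p")
  co <- tibble::tibble(cell_id = rownames(v), common_u = u)
  pr <- feature_profile(x, co, c("lin", "const", "noisy"))
  lin <- pr[pr$feature == "lin" & !is.na(pr$mean), ]
  expect_equal(cor(lin$mean, lin$u, method = "spearman"), 1)
  expect_true(all(lin$lo <= lin$mean & lin$mean <= lin$hi))
  cst <- pr[pr$feature == "const", ]
  expect_true(all(cst$degenerate))
  expect_true(all(cst$mean[!is.na(cst$mean)] == 0))
  # confidence bands shrink roughly as 1/sqrt(n): double the cells
  u2 <- c(u, runif(n)); v2 <- rbind(v, cbind(lin = 2 + 3 * u2[(n + 1):(2 * n)],
                                             const = 5,
                                             noisy = 1 + u2[(n + 1):(2 * n)] +
                                               rnorm(n, 0, 0.1)))
  rownames(v2) <- sprintf("c%03d", seq_len(2 * n))
  co2 <- tibble::tibble(cell_id = rownames(v2), common_u = u2)
  pr2 <- feature_profile(mk_scm(v2, "rna", "normalized_log1p"), co2, "noisy")
  w1 <- median(pr$hi[pr$feature == "noisy"] - pr$lo[pr$feature == "noisy"],
               na.rm = TRUE)
  w2 <- median(pr2$hi - pr2$lo, na.rm = TRUE)
  expect_lt(abs(w2 / w1 - 1 / sqrt(2)), 0.15)
})

test_that("onset estimation interpolates the half-of-final crossing", {
  sm <- tibble::tibble(time_point_h = c(0, 1, 2, 4, 8),
                       median_u = c(0, 0.1, 0.3, 0.7, 0.9))
  # identical summaries give exactly zero lag
  ol <- estimate_onset_lag(sm, sm)
  expect_equal(ol$lag_h, 0)
  # hand-computed crossing of 0.45: between t = 2 and 4
  expect_equal(ol$onset_rna_h, 2 + (0.45 - 0.3) / 0.4 * 2)
  # shifted protein summary gives the planted lag
  sm_p <- tibble::tibble(time_point_h = c(0, 1, 2, 4, 8),
                         median_u = c(0, 0.02, 0.1, 0.48, 0.9))
  ol2 <- estimate_onset_lag(sm, sm_p)
  expect_gt(ol2$lag_h, 0)
  # a baseline offset does not fake an early onset: the rule is
  # baseline-relative, so shifting the whole curve leaves the onset unchanged
  sm_off <- dplyr::mutate(sm, median_u = median_u + 0.4)
  expect_equal(estimate_onset_lag(sm_off, sm_off)$onset_rna_h, ol$onset_rna_h)
  # flat trajectory: onset undefined and flagged
  flat <- tibble::tibble(time_point_h = c(0, 2, 8), median_u = c(0, 0, 0))
  expect_error(estimate_onset_lag(sm[1:2, ], sm), ">= 3 time points")
  ol3 <- estimate_onset_lag(sm, flat)
  expect_true(is.na(ol3$onset_prot_h))
  expect_true(attr(ol3, "undefined")[["protein"]])
})

test_that("fast and slow anchors demarcate ordered response zones", {
  grid <- seq(0, 1, length.out = 100)
  logi <- function(mid) 1.2 * stats::plogis((grid - mid) / 0.02) - 0.1
  pr <- dplyr::bind_rows(
    tibble::tibble(feature = "fast", modality = "rna", u = grid,
                   mean = logi(0.4), lo = NA, hi = NA, n = 50L,
                   degenerate = FALSE),
    tibble::tibble(feature = "slow", modality = "rna", u = grid,
                   mean = logi(0.7), lo = NA, hi = NA, n = 50L,
                   degenerate = FALSE),
    tibble::tibble(feature = "flat", modality = "rna", u = grid,
                   mean = rep(0, 100), lo = NA, hi = NA, n = 50L,
                   degenerate = FALSE))
  z <- demarcate_zones(pr, "fast", "slow")
  expect_lt(abs(z$u_pre - 0.4), 0.05)
  expect_lt(abs(z$u_onset - 0.7), 0.05)
  expect_true(z$u_pre <= z$u_onset)
  zf <- demarcate_zones(pr, "flat", "slow")
  expect_true(is.na(zf$u_pre))
  expect_true(zf$undefined[["pre"]])
})

test_that("the estimated lag collapses when protein kinetics are fast", {
  res <- run_pipeline(pipeline_config(
    seed = 3, generator = generator_config(k_deg = 20)))  # nominal lag 0.035 h
  expect_lt(abs(res$onset$lag_h), 0.5)
})

test_that("lag recovery and zone ordering hold end to end on default data", {
  res <- cached_run(1)
  expect_false(inherits(res, "failed_run"))
  expect_gt(res$onset$lag_h, 0)                      # proteome trails
  expect_true(res$zones$u_pre <= res$zones$u_onset)  # fast markers cross first
  # profiles of abundant proteins are stable to imputation
  sim <- simulate_experiment({g <- generator_config(); g$seed <- 1; g})
  th <- pipeline_config(seed = 1)$thresholds
  qp <- filter_cells(sim$prot$mat, sim$prot$ann, th)
  np0 <- normalize_log1p(qp$mat)
  keep <- res$subpop$clusters_prot$cell_id[!res$subpop$clusters_prot$candidate_subpop]
  np0k <- pseudolign:::scm_subset(np0, cells = cell_ids(np0) %in% keep)
  ab <- colMeans(scm_values(qp$mat), na.rm = TRUE)
  topq <- names(ab)[ab >= stats::quantile(ab, 0.75)]
  pr_imp <- feature_profile(res$prot$mat, res$warp$coords,
                            intersect(topq, feature_ids(res$prot$mat)))
  pr_raw <- feature_profile(np0k, res$warp$coords,
                            intersect(topq, feature_ids(np0k)))
  j <- dplyr::inner_join(pr_imp, pr_raw, by = c("feature", "u"))
  cc <- j |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(r = stats::cor(.data$mean.x, .data$mean.y,
                                    use = "complete.obs"))
  expect_gte(median(cc$r, na.rm = TRUE), 0.9)
})
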