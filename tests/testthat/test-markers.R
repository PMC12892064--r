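# brute-force definitions used as independent oracles
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
holm_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(p[o] * (m - seq_len(m) + 1))
  pmin(adj, 1)[order(o)]
}

test_that("BH and Holm adjustments match hand computations and brute force", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "Holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "Holm"), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "BH"), bh_bruteforce(p))
    expect_equal(adjust_pvalues(p, "Holm"), holm_bruteforce(p))
  }
})

test_that("Wilcoxon DE matches the exact distribution on small groups", {
  v <- cbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = c(4, 6, 5, 1, 3, 2))
  rownames(v) <- paste0("c", 1:6)
  x <- mk_scm(v, "rna", "normalized_log1p")
  de <- wilcoxon_de(x, groups = rep(c("A", "B"), each = 3))
  a <- de[de$group == "A", ]
  expect_equal(unname(a$stat[a$feature == "f1"]), 0)           # {1,2,3} vs {4,5,6}
  expect_equal(unname(a$p[a$feature == "f1"]), 0.1)            # exact two-sided
  expect_equal(unname(a$p[a$feature == "f2"]), 0.1)            # symmetric case
  # identical multisets in both groups: log2FC 0, p 1
  v2 <- cbind(g = c(1, 2, 3, 1, 2, 3))
  rownames(v2) <- paste0("c", 1:6)
  de2 <- wilcoxon_de(mk_scm(v2, "rna", "normalized_log1p"),
                     rep(c("A", "B"), each = 3))
  expect_equal(unname(de2$log2fc), c(0, 0))
  expect_equal(unname(de2$p), c(1, 1))
  # small-group contrast skipped with a warning
  w <- capture_warnings(
    wilcoxon_de(x, groups = c("A", "A", "A", "A", "B", "B")))
  expect_true(any(grepl("fewer than 3", w)))
})

test_that("normal approximation tracks the exact Wilcoxon distribution", {
  # full enumeration over all U values for tie-free groups of size <= 8:
  # the approximation is accurate in the bulk and within the known
  # tail envelope of the uncorrected normal approximation
  devs <- c()
  for (n1 in 4:8) for (n2 in 4:8) {
    us <- 0:(n1 * n2)
    exact <- vapply(us, function(u) {
      min(1, 2 * min(stats::pwilcox(u, n1, n2),
                     1 - stats::pwilcox(u - 1, n1, n2)))
    }, numeric(1))
    rks <- seq_len(n1 + n2)   # tie-free ranks
    approx <- vapply(us, function(u) pseudolign:::mwu_normal_p(u, n1, n2, rks),
                     numeric(1))
    devs <- c(devs, abs(exact - approx))
  }
  expect_lt(max(devs), 0.13)
  expect_lt(median(devs), 0.03)
})

test_that("planted subpopulation features pass the DE significance gates", {
  sim <- simulate_experiment(generator_config(seed = 4))
  nr <- normalize_log1p(sim$rna$mat)
  tr <- sim$truth$cells_rna
  grp <- ifelse(tr$subpop[match(cell_ids(nr), tr$cell_id)], "small", "large")
  de <- wilcoxon_de(nr, grp, preset = "subpopulation")
  de <- de[de$group == "small", ]
  spf <- sim$truth$features$feature_id[sim$truth$features$subpop_amplitude > 0]
  expect_gte(mean(de$significant[de$feature %in% spf]), 0.8)
})

test_that("LRT ranking is calibrated, shift-invariant and matches lm()", {
  # type-I error on pure-noise features
  set.seed(21)
  n <- 150
  v <- matrix(rnorm(n * 1000, 5, 1), n, 1000,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("g%04d", 1:1000)))
  phase <- sample(c("G0/G1", "S", "G2/M"), n, replace = TRUE)
  tp <- sample(c(0, 2, 4, 8), n, replace = TRUE)
  x <- mk_scm(v, "rna", "normalized_log1p")
  res <- lrt_rank_markers(x, phase, tp, K = 10)
  frac <- mean(res$table$p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  expect_true(all(res$table$df == 3))
  expect_true(all(res$table$lambda >= 0))
  expect_setequal(res$table$rank, seq_len(1000))

  # power: planted 2-log-unit time effect, sd 1, 50 cells per time point
  for (s in 1:10) {
    set.seed(s)
    tp2 <- rep(c(0, 2, 4, 8), each = 50)
    ph2 <- sample(c("G0/G1", "S"), 200, replace = TRUE)
    y <- rnorm(200, 5, 1) + 2 * (tp2 > 0)
    vv <- cbind(sig = y, null = rnorm(200, 5, 1))
    rownames(vv) <- sprintf("c%03d", 1:200)
    r2 <- lrt_rank_markers(mk_scm(vv, "rna", "normalized_log1p"), ph2, tp2, K = 1)
    expect_lt(r2$table$p_adj[r2$table$feature == "sig"], 1e-4)
    expect_identical(as.character(r2$markers), "sig")
  }

  # Lambda invariant to adding a constant to a feature
  v2 <- v[, 1:5]; v2[, 1] <- v2[, 1] + 100
  r3 <- lrt_rank_markers(mk_scm(v2, "rna", "normalized_log1p"), phase, tp, K = 2)
  r4 <- lrt_rank_markers(mk_scm(v[, 1:5], "rna", "normalized_log1p"), phase, tp, K = 2)
  expect_equal(unname(r3$table$lambda[r3$table$feature == "g0001"]),
               unname(r4$table$lambda[r4$table$feature == "g0001"]),
               tolerance = 1e-8)

  # per-feature lm/logLik oracle
  y1 <- v[, 3]
  full <- stats::lm(y1 ~ factor(phase) + factor(tp))
  red <- stats::lm(y1 ~ factor(phase))
  lam_oracle <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(red)))
  expect_equal(unname(res$table$lambda[res$table$feature == "g0003"]),
               lam_oracle, tolerance = 1e-6)
})

test_that("marker selection is deterministic and overlaps are exact", {
  sim <- simulate_experiment(tiny_config(seed = 6))
  nr <- normalize_log1p(sim$rna$mat)
  tr <- sim$truth$cells_rna
  a <- lrt_rank_markers(nr, tr$phase_true, tr$time_point_h, K = 8)
  b <- lrt_rank_markers(nr, tr$phase_true, tr$time_point_h, K = 8)
  expect_identical(as.character(a$markers), as.character(b$markers))

  ov <- marker_overlap(list(x = c("A", "B", "C"), y = c("B", "C", "D")))
  expect_equal(ov$pairwise$intersection, 2)
  expect_equal(ov$pairwise$union, 4)
  ov2 <- marker_overlap(list(x = c("A", "B"), y = c("A", "B"), z = c("C", "D")))
  pw <- ov2$pairwise
  expect_equal(pw$intersection[pw$set1 == "x" & pw$set2 == "y"], 2)
  expect_equal(pw$intersection[pw$set1 == "x" & pw$set2 == "z"], 0)
  expect_error(marker_overlap(list(c("A"))), "two sets")
  expect_error(marker_set(c("A", "A"), "rna", "hypoxia"), "duplicates")
})

test_that("graph clustering separates constructed clouds and is deterministic", {
  set.seed(8)
  v <- rbind(matrix(rnorm(100 * 2, 0, 0.1), 100, 2),
             matrix(rnorm(100 * 2, 10, 0.1), 100, 2))
  rownames(v) <- sprintf("c%03d", 1:200); colnames(v) <- c("f1", "f2")
  x <- mk_scm(pmax(v, 0), "rna", "normalized_log1p")
  cl <- cluster_cells(x, n_neighbors = 10, resolution = 0.05, seed = 3)
  truth <- rep(1:2, each = 100)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(ari(cl$cluster, truth), 1)
  cl2 <- cluster_cells(x, n_neighbors = 10, resolution = 0.05, seed = 3)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_cells(x, n_neighbors = 300), "fewer cells")
})

test_that("composition tables are normalized and chi-square matches by hand", {
  cl <- tibble::tibble(cell_id = sprintf("c%02d", 1:40),
                       cluster = rep(1:2, each = 20))
  ann <- tibble::tibble(cell_id = cl$cell_id,
                        phase = rep(c("G0/G1", "S"), 20))
  out <- composition_table(cl, ann)
  # balanced 2x2 contingency: statistic 0, p 1
  expect_equal(out$tests$statistic, 0)
  expect_equal(out$tests$p, 1)
  sums <- tapply(out$proportions$proportion, out$proportions$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single cluster reproduces the global distribution
  one <- composition_table(dplyr::mutate(cl, cluster = 1), ann)
  expect_true(all(abs(one$proportions$proportion - 0.5) < 1e-12))
})

test_that("fold-change concordance recovers the planted discordant fraction", {
  de <- tibble::tibble(feature = c("a", "b", "c"), group = "g",
                       stat = 1, p = 0.001, p_adj = 0.001,
                       log2fc = c(1, -2, 0.5), significant = TRUE)
  self <- mutual_de_concordance(de, de)
  expect_equal(attr(self, "sign_agreement"), 1)
  empty <- de[0, ]
  expect_warning(none <- mutual_de_concordance(de, empty), "no mutually")
  expect_equal(nrow(none), 0)

  # truth-label DE against generator with discordant fraction 0.4
  agrees <- vapply(1:5, function(s) {
    sim <- simulate_experiment(generator_config(seed = 20 + s,
                                                subpop_discordant_fraction = 0.4))
    nr <- normalize_log1p(sim$rna$mat)
    np <- knn_impute(normalize_log1p(sim$prot$mat), 5)
    gr <- function(cells, ids) ifelse(cells$subpop[match(ids, cells$cell_id)],
                                      "small", "large")
    de_r <- wilcoxon_de(nr, gr(sim$truth$cells_rna, cell_ids(nr)))
    de_p <- wilcoxon_de(np, gr(sim$truth$cells_prot, cell_ids(np)))
    conc <- mutual_de_concordance(de_r[de_r$group == "small", ],
                                  de_p[de_p$group == "small", ])
    attr(conc, "sign_agreement")
  }, numeric(1))
  expect_lt(abs(mean(agrees) - 0.6), 0.1)
})
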