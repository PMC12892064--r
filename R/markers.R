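#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up FDR or Holm step-down FWER adjustment, input
#' order preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"Holm"`.
#' @return adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = c(BH = "BH", Holm = "holm")[[method]])
}

# significance preset profiles used in the analyses
#' @rdname wilcoxon_de
#' @export
de_presets <- list(
  subpopulation = list(p_adj_max = 0.05, min_abs_log2fc = 0.2),
  covariate_markers = list(p_adj_max = 0.01, min_abs_log2fc = 0.37)
)

# tie-corrected normal-approximation Mann-Whitney p for one feature
mwu_normal_p <- function(u, n1, n2, ranks_all) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(ranks_all)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (u - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon (Mann-Whitney) differential expression
#'
#' Two-sided Mann-Whitney U test per feature and group, one-vs-rest or all
#' pairwise contrasts. Uses the exact distribution when both group sizes are
#' at most 8 (and the data are tie-free), otherwise the tie-corrected normal
#' approximation. Log2 fold change is the difference of group means of
#' log2-scale expression. BH correction is applied across features within
#' each contrast.
#'
#' @param x normalized `scm`.
#' @param groups character/factor vector of cell labels aligned to the cells
#'   of `x` (or a 2-column tibble `cell_id`, `group`).
#' @param scheme `"one_vs_rest"` or `"pairwise"`.
#' @param preset one of `names(de_presets)`, or a list with `p_adj_max` and
#'   `min_abs_log2fc`, controlling the `significant` flag.
#' @return tibble: feature, group (contrast label), stat (U), p, p_adj,
#'   log2fc, significant.
#' @export
wilcoxon_de <- function(x, groups, scheme = c("one_vs_rest", "pairwise"),
                        preset = "subpopulation") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "scm"))
  if (x$transform == "raw") stop("expected a normalized matrix", call. = FALSE)
  if (is.data.frame(groups)) {
    groups <- groups$group[match(cell_ids(x), groups$cell_id)]
  }
  stopifnot(length(groups) == n_cells(x))
  if (is.character(preset)) preset <- de_presets[[match.arg(preset, names(de_presets))]]
  v <- scm_values(x)
  has_na <- colSums(is.na(v)) > 0
  if (any(has_na)) {
    warning(sum(has_na), " feature(s) with missing values dropped from DE")
    v <- v[, !has_na, drop = FALSE]
  }
  lv <- sort(unique(as.character(groups)))
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  contrasts <- if (scheme == "one_vs_rest") {
    lapply(lv, function(g) list(label = g, a = groups == g, b = groups != g))
  } else {
    prs <- utils::combn(lv, 2, simplify = FALSE)
    lapply(prs, function(pr) list(label = paste(pr, collapse = "_vs_"),
                                  a = groups == pr[1], b = groups == pr[2]))
  }
  out <- lapply(contrasts, function(ct) {
    n1 <- sum(ct$a); n2 <- sum(ct$b)
    if (n1 < 3 || n2 < 3) {
      warning("contrast ", ct$label, " skipped: group with fewer than 3 cells")
      return(NULL)
    }
    sel <- ct$a | ct$b
    ia <- ct$a[sel]
    res <- apply(v[sel, , drop = FALSE], 2, function(col) {
      xa <- col[ia]
      xb <- col[!ia]
      rks <- rank(c(xa, xb))
      u <- sum(rks[seq_along(xa)]) - n1 * (n1 + 1) / 2
      if (n1 <= 8 && n2 <= 8 && !anyDuplicated(c(xa, xb))) {
        p <- stats::wilcox.test(xa, xb, exact = TRUE)$p.value
      } else {
        p <- mwu_normal_p(u, n1, n2, rks)
      }
      c(u = u, p = p)
    })
    # natural-log1p values: difference of means rescaled to log2
    lfc <- (colMeans(v[ct$a, , drop = FALSE]) - colMeans(v[ct$b, , drop = FALSE])) / log(2)
    tibble::tibble(feature = colnames(v), group = ct$label,
                   stat = res["u", ], p = res["p", ],
                   p_adj = adjust_pvalues(res["p", ], "BH"), log2fc = lfc)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) {
    out$significant <- out$p_adj <= preset$p_adj_max &
      abs(out$log2fc) >= preset$min_abs_log2fc
  }
  out
}

#' Ordered marker set
#'
#' @param features ordered feature ids (no duplicates).
#' @param modality,covariate provenance labels.
#' @param rule selection-rule description.
#' @return a `marker_set` (character vector with metadata attributes).
#' @export
marker_set <- function(features, modality, covariate, rule = "top-K by adjusted p") {
  if (anyDuplicated(features)) stop("marker set must not contain duplicates", call. = FALSE)
  structure(as.character(features), class = "marker_set",
            modality = modality, covariate = covariate, rule = rule)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s/%s: %d features (%s)\n", attr(x, "modality"),
              attr(x, "covariate"), length(x), attr(x, "rule")))
  invisible(x)
}

#' Likelihood-ratio ranking of stimulus markers
#'
#' Per feature, ordinary-least-squares Gaussian fits of normalized log
#' expression on cell-cycle phase (reduced model) and on phase plus
#' categorical time point (full model). The statistic is
#' `Lambda = 2 (loglik_full - loglik_reduced)`, chi-square distributed with
#' `(time levels - 1)` degrees of freedom under the null; Holm correction is
#' applied across features and features are ranked by adjusted p (ties broken
#' by larger Lambda, then feature id). Time levels with fewer than 2 cells
#' are merged with the nearest level (with a warning).
#'
#' @param x normalized (protein: imputed) `scm`.
#' @param phase,time_point vectors aligned to the cells of `x`.
#' @param K size of the selected marker set.
#' @return list: `table` (tibble: feature, lambda, df, p, p_adj, rank,
#'   direction), `markers` (a [marker_set()] of the top `K`).
#' @export
lrt_rank_markers <- function(x, phase, time_point, K = 50L) {
  stopifnot(inherits(x, "scm"), length(phase) == n_cells(x),
            length(time_point) == n_cells(x))
  if (x$transform == "raw") stop("expected a normalized matrix", call. = FALSE)
  if (K > n_features(x)) stop("K exceeds the number of features", call. = FALSE)
  tp <- as.numeric(time_point)
  tab <- table(tp)
  small <- as.numeric(names(tab))[tab < 2]
  for (s in small) {
    others <- setdiff(as.numeric(names(table(tp))), s)
    nearest <- others[which.min(abs(others - s))]
    warning("time level ", s, " has < 2 cells; merged with ", nearest)
    tp[tp == s] <- nearest
  }
  ft <- factor(tp)
  fp <- factor(phase)
  if (nlevels(ft) < 2) stop("need at least two time levels", call. = FALSE)
  y <- scm_values(x)
  has_na <- colSums(is.na(y)) > 0
  if (any(has_na)) {
    warning(sum(has_na), " feature(s) with missing values dropped from LRT")
    y <- y[, !has_na, drop = FALSE]
  }
  n <- nrow(y)
  x_red <- stats::model.matrix(~fp)
  x_full <- stats::model.matrix(~ fp + ft)
  rss <- function(xm) {
    q <- qr.Q(qr(xm))
    r <- y - q %*% crossprod(q, y)
    colSums(r^2)
  }
  rss_red <- rss(x_red)
  rss_full <- rss(x_full)
  lambda <- n * log(pmax(rss_red, 1e-300) / pmax(rss_full, 1e-300))
  lambda <- pmax(lambda, 0)
  df <- nlevels(ft) - 1L
  p <- stats::pchisq(lambda, df, lower.tail = FALSE)
  p_adj <- adjust_pvalues(p, "Holm")
  direction <- sign(as.vector(stats::cor(tp, y)))
  tab <- tibble::tibble(feature = colnames(y), lambda = lambda, df = df,
                        p = p, p_adj = p_adj, direction = direction)
  ord <- order(tab$p_adj, -tab$lambda, tab$feature)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  ms <- marker_set(tab$feature[ord][seq_len(K)], x$modality, "hypoxia",
                   sprintf("top-%d by Holm-adjusted LRT p", K))
  list(table = tab[ord, ], markers = ms)
}

#' Overlap between marker sets
#'
#' Exact pairwise intersection cardinalities and the full membership-pattern
#' (Venn) partition over two or more marker sets.
#'
#' @param sets named list of [marker_set()]s (or character vectors).
#' @return list: `pairwise` (tibble: set1, set2, intersection, union,
#'   jaccard), `partition` (tibble: one indicator column per set, n).
#' @export
marker_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  prs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(prs, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    int <- length(intersect(a, b)); uni <- length(union(a, b))
    tibble::tibble(set1 = pr[1], set2 = pr[2], intersection = int,
                   union = uni, jaccard = if (uni > 0) int / uni else NA_real_)
  })
  all_feats <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_feats %in% s, logical(length(all_feats)))
  memb <- as.data.frame(memb)
  partition <- dplyr::count(memb, dplyr::across(dplyr::everything()), name = "n")
  list(pairwise = pairwise, partition = tibble::as_tibble(partition))
}

#' Graph-community clustering of cells
#'
#' Leiden modularity clustering on the unweighted symmetric k-NN graph of the
#' expression matrix. The smallest cluster is flagged as the candidate
#' subpopulation when it holds fewer than 25% of cells.
#'
#' @param x normalized (protein: imputed) `scm`.
#' @param n_neighbors neighbors of the k-NN graph.
#' @param resolution Leiden resolution (modularity objective).
#' @param scale_features z-score features before building the graph
#'   (default), so high-abundance features do not dominate distances.
#' @param seed RNG seed (labels are deterministic given the seed).
#' @return tibble: cell_id, cluster (integer), candidate_subpop (logical).
#' @export
cluster_cells <- function(x, n_neighbors = 15L, resolution = 0.25, seed = 1L,
                          scale_features = TRUE) {
  stopifnot(inherits(x, "scm"))
  if (n_cells(x) <= n_neighbors) {
    stop("fewer cells than n_neighbors", call. = FALSE)
  }
  v <- scm_values(x)
  all_na <- colSums(!is.na(v)) == 0
  if (any(all_na)) v <- v[, !all_na, drop = FALSE]   # never-observed features
  if (anyNA(v)) stop("matrix has missing values; impute first", call. = FALSE)
  if (scale_features) {
    sds <- apply(v, 2, stats::sd)
    v <- sweep(sweep(v, 2, colMeans(v)), 2, pmax(sds, 1e-12), `/`)
  }
  d2 <- as.matrix(stats::dist(v))^2
  n <- nrow(v)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(n_neighbors + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  lab <- as.integer(igraph::membership(cl))
  sizes <- table(lab)
  smallest <- as.integer(names(sizes)[which.min(sizes)])
  flag <- length(sizes) > 1 && min(sizes) < 0.25 * n
  tibble::tibble(cell_id = rownames(v), cluster = lab,
                 candidate_subpop = flag & lab == smallest)
}

#' Cluster composition by phase and time point
#'
#' Per-cluster proportions of cell-cycle phase and sampling time, with
#' chi-square homogeneity tests of cluster vs phase and cluster vs time.
#'
#' @param clusters tibble from [cluster_cells()] (cell_id, cluster).
#' @param ann annotation tibble with `cell_id`, `phase` and/or
#'   `time_point_h`.
#' @return list: `proportions` (tibble: cluster, covariate, level,
#'   proportion), `tests` (tibble: covariate, statistic, df, p).
#' @export
composition_table <- function(clusters, ann) {
  d <- dplyr::inner_join(clusters, ann, by = "cell_id")
  covs <- intersect(c("phase", "time_point_h"), names(d))
  props <- purrr::map_dfr(covs, function(cv) {
    d |>
      dplyr::count(.data$cluster, level = as.character(.data[[cv]])) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(proportion = .data$n / sum(.data$n), covariate = cv) |>
      dplyr::ungroup() |>
      dplyr::select("cluster", "covariate", "level", "proportion")
  })
  tests <- purrr::map_dfr(covs, function(cv) {
    ct <- table(d$cluster, d[[cv]])
    if (nrow(ct) < 2 || ncol(ct) < 2) {
      return(tibble::tibble(covariate = cv, statistic = 0, df = 0L, p = 1))
    }
    ch <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
    tibble::tibble(covariate = cv, statistic = unname(ch$statistic),
                   df = unname(ch$parameter), p = ch$p.value)
  })
  list(proportions = props, tests = tests)
}

#' Fold-change concordance of mutually differentially expressed features
#'
#' Inner-joins the significant features of an RNA and a protein DE table
#' (optionally through a feature id map) and reports paired log2 fold changes
#' and the fraction agreeing in sign. When a table carries several contrasts
#' per feature, the row with the smallest adjusted p is used.
#'
#' @param de_rna,de_prot DE tables from [wilcoxon_de()].
#' @param id_map optional tibble with columns `feature_rna`, `feature_prot`;
#'   default maps identical ids (shared gene symbols).
#' @return tibble: feature_rna, feature_prot, log2fc_rna, log2fc_prot,
#'   concordant; attribute `sign_agreement`.
#' @export
mutual_de_concordance <- function(de_rna, de_prot, id_map = NULL) {
  pick <- function(de) {
    de |>
      dplyr::filter(.data$significant) |>
      dplyr::group_by(.data$feature) |>
      dplyr::slice_min(.data$p_adj, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  a <- pick(de_rna)
  b <- pick(de_prot)
  if (is.null(id_map)) {
    id_map <- tibble::tibble(feature_rna = union(a$feature, b$feature))
    id_map$feature_prot <- id_map$feature_rna
  }
  out <- id_map |>
    dplyr::inner_join(dplyr::select(a, feature_rna = "feature",
                                    log2fc_rna = "log2fc"), by = "feature_rna") |>
    dplyr::inner_join(dplyr::select(b, feature_prot = "feature",
                                    log2fc_prot = "log2fc"), by = "feature_prot") |>
    dplyr::mutate(concordant = sign(.data$log2fc_rna) == sign(.data$log2fc_prot))
  if (!nrow(out)) warning("no mutually significant features")
  attr(out, "sign_agreement") <- if (nrow(out)) mean(out$concordant) else NA_real_
  out
}
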