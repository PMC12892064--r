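#' Quality-control thresholds
#'
#' Default gates: protein cells kept when `15 < log2(sum S/N) < 17.5` and at
#' least 850 proteins are identified; RNA cells kept with at least 8000 counts
#' and a detected-gene count in `[300, 10000]`, after which genes detected in
#' fewer than 10 retained cells are dropped. The protein/gene minimum-feature
#' gates are panel-size dependent and should be scaled when the feature panel
#' is small (e.g. simulated data).
#'
#' @param prot_log2sn_low,prot_log2sn_high open interval for the per-cell
#'   log2 summed reporter S/N.
#' @param prot_min_features minimum proteins identified per cell.
#' @param rna_min_counts minimum total counts per RNA cell.
#' @param rna_gene_min_cells genes must be detected in at least this many
#'   retained cells.
#' @param rna_min_genes,rna_max_genes detected-gene count range per RNA cell.
#' @param target_sum per-cell target sum for normalization.
#' @param impute_k neighbors for protein k-NN imputation.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(prot_log2sn_low = 15, prot_log2sn_high = 17.5,
                          prot_min_features = 850,
                          rna_min_counts = 8000, rna_gene_min_cells = 10,
                          rna_min_genes = 300, rna_max_genes = 10000,
                          target_sum = 1e4, impute_k = 5L) {
  stopifnot(prot_log2sn_low < prot_log2sn_high, prot_min_features > 0,
            rna_min_counts > 0, rna_gene_min_cells > 0,
            rna_min_genes > 0, rna_max_genes > rna_min_genes,
            target_sum > 0, impute_k >= 1)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Filter cells (and rare genes) by the QC gates
#'
#' Protein: keep cells with `log2(sum S/N)` strictly inside the configured
#' interval and at least `prot_min_features` observed proteins. RNA: keep
#' cells with at least `rna_min_counts` total counts and a detected-gene count
#' inside `[rna_min_genes, rna_max_genes]`, then drop genes detected in fewer
#' than `rna_gene_min_cells` of the retained cells.
#'
#' @param x an `scm` with raw values.
#' @param ann annotation tibble aligned to the cells of `x`.
#' @param thresholds a [qc_thresholds()].
#' @return list: `mat` (filtered `scm`), `ann` (filtered, QC stats
#'   recomputed), `report` (tibble: rule, removed).
#' @export
filter_cells <- function(x, ann, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "scm"), inherits(thresholds, "qc_thresholds"))
  ann <- check_alignment(x, ann)
  qc <- annotate_cells(x)
  th <- thresholds
  if (x$modality == "protein") {
    ok_sn <- !is.na(qc$log2_sum_sn) &
      qc$log2_sum_sn > th$prot_log2sn_low & qc$log2_sum_sn < th$prot_log2sn_high
    ok_nf <- qc$n_features_detected >= th$prot_min_features
    keep <- ok_sn & ok_nf
    report <- tibble::tibble(
      rule = c("log2_sum_sn_out_of_range", "too_few_proteins", "cells_retained"),
      removed = c(sum(!ok_sn), sum(ok_sn & !ok_nf), NA_integer_),
      retained = c(NA_integer_, NA_integer_, sum(keep))
    )
    out <- scm_subset(x, cells = keep)
  } else {
    ok_counts <- qc$total_counts >= th$rna_min_counts
    ok_genes <- qc$n_features_detected >= th$rna_min_genes &
      qc$n_features_detected <= th$rna_max_genes
    keep <- ok_counts & ok_genes
    out <- scm_subset(x, cells = keep)
    det_cells <- colSums(scm_values(out) > 0)
    keep_gene <- det_cells >= th$rna_gene_min_cells
    out <- scm_subset(out, features = keep_gene)
    report <- tibble::tibble(
      rule = c("too_few_counts", "gene_count_out_of_range",
               "gene_detected_in_too_few_cells", "cells_retained"),
      removed = c(sum(!ok_counts), sum(ok_counts & !ok_genes),
                  sum(!keep_gene), NA_integer_),
      retained = c(NA_integer_, NA_integer_, NA_integer_, sum(keep))
    )
  }
  ann2 <- annotate_cells(out, ann[ann$cell_id %in% cell_ids(out), , drop = FALSE])
  list(mat = out, ann = ann2, report = report)
}

#' Target-sum normalization followed by log1p
#'
#' Scales each cell's observed (non-missing) values so that they sum to
#' `target_sum`, then applies `log(x + 1)`. Missing protein entries stay
#' missing. Cells whose observed values sum to zero cannot be scaled; they are
#' dropped with a warning and listed in the `dropped_cells` attribute.
#'
#' @param x an `scm` with raw values.
#' @param target_sum positive scale (default `1e4`).
#' @return normalized `scm` (transform state `normalized_log1p`).
#' @export
normalize_log1p <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "scm"), target_sum > 0)
  if (x$transform != "raw") stop("expected a raw matrix", call. = FALSE)
  v <- scm_values(x)
  sums <- rowSums(v, na.rm = TRUE)
  bad <- sums <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with no observed signal dropped before normalization")
    v <- v[!bad, , drop = FALSE]
    sums <- sums[!bad]
  }
  v <- log1p(v / sums * target_sum)
  out <- x
  out$values <- v
  out <- advance_transform(out, "normalized_log1p")
  attr(out, "dropped_cells") <- rownames(scm_values(x))[bad]
  out
}

# masked pairwise squared Euclidean distances over mutually observed
# features, rescaled to the full feature count; pairs with fewer than
# `min_overlap` mutual features get Inf.
masked_dist2 <- function(v, min_overlap) {
  m <- !is.na(v)
  x0 <- v
  x0[!m] <- 0
  a <- tcrossprod(x0)
  b <- tcrossprod(x0^2, m)
  d2 <- b + t(b) - 2 * a
  d2[d2 < 0] <- 0
  cnt <- tcrossprod(m * 1)
  d2 <- d2 * ncol(v) / pmax(cnt, 1)
  d2[cnt < min_overlap] <- Inf
  diag(d2) <- 0
  d2
}

#' k-nearest-neighbor imputation of missing protein values
#'
#' Each missing entry is replaced by the unweighted mean of that feature's
#' observed values among the cell's `k` nearest neighbors. Distances are
#' Euclidean over mutually observed features (rescaled to the panel size),
#' with pairs sharing fewer than `min_overlap` features excluded as neighbor
#' candidates. Entries observed in no neighbor fall back to the feature's
#' global observed mean (flagged); features observed nowhere are left missing
#' and reported. Observed entries are never altered.
#'
#' @param x normalized protein `scm` with a missing mask.
#' @param k positive neighbor count, `k < n_cells`.
#' @param min_overlap minimum mutually observed features for a usable
#'   neighbor distance.
#' @return imputed `scm`; attributes `imputed_mask` (logical matrix),
#'   `fallback_mask` (global-mean fills) and `unimputable_features`.
#' @export
knn_impute <- function(x, k = 5L, min_overlap = 20L) {
  stopifnot(inherits(x, "scm"))
  if (x$transform != "normalized_log1p") {
    stop("expected a normalized matrix", call. = FALSE)
  }
  if (k >= n_cells(x)) stop("k must be smaller than the number of cells", call. = FALSE)
  v <- scm_values(x)
  miss <- is.na(v)
  if (!any(miss)) {
    out <- advance_transform(x, "imputed")
    attr(out, "imputed_mask") <- miss
    return(out)
  }
  d2 <- masked_dist2(v, min_overlap)
  gmean <- colMeans(v, na.rm = TRUE)
  never <- colSums(!miss) == 0
  filled <- v
  fallback <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) {
    gi <- which(miss[i, ] & !never)
    if (!length(gi)) next
    ord <- order(d2[i, ])
    ord <- setdiff(ord, i)
    ord <- ord[is.finite(d2[i, ord])]
    nb <- ord[seq_len(min(k, length(ord)))]
    if (length(nb)) {
      nbv <- v[nb, gi, drop = FALSE]
      est <- colMeans(nbv, na.rm = TRUE)
    } else {
      est <- rep(NaN, length(gi))
    }
    nofill <- !is.finite(est)
    est[nofill] <- gmean[gi][nofill]
    fallback[i, gi[nofill]] <- TRUE
    filled[i, gi] <- est
  }
  out <- x
  out$values <- filled
  out <- advance_transform(out, "imputed")
  attr(out, "imputed_mask") <- miss & !is.na(filled)
  attr(out, "fallback_mask") <- fallback
  attr(out, "unimputable_features") <- colnames(v)[never]
  out
}

#' Cell-cycle phase from FUCCI reporter intensities
#'
#' Quadrant gate on the two reporters: mAzamiGreen-high / mMaroon1-low cells
#' are G0/G1, red-high/green-low are S, both-high are G2/M, both-low are
#' unassigned. Default gates sit at each reporter's 50th percentile.
#'
#' @param ann annotation tibble with `fucci_green` and `fucci_red` columns.
#' @param green_gate,red_gate intensity thresholds; `NULL` = per-reporter
#'   median.
#' @return `ann` with a `phase` column added (and the gates as attributes).
#' @export
assign_phase_from_fucci <- function(ann, green_gate = NULL, red_gate = NULL) {
  if (!all(c("fucci_green", "fucci_red") %in% names(ann))) {
    stop("annotations must carry fucci_green and fucci_red columns", call. = FALSE)
  }
  if (is.null(green_gate)) green_gate <- stats::median(ann$fucci_green, na.rm = TRUE)
  if (is.null(red_gate)) red_gate <- stats::median(ann$fucci_red, na.rm = TRUE)
  g <- ann$fucci_green > green_gate
  r <- ann$fucci_red > red_gate
  ann$phase <- dplyr::case_when(
    g & !r ~ "G0/G1",
    r & !g ~ "S",
    g & r ~ "G2/M",
    .default = "unassigned"
  )
  attr(ann, "fucci_gates") <- c(green = green_gate, red = red_gate)
  ann
}

#' Marker-based cell-cycle scoring for RNA cells
#'
#' For each marker set the score is the mean normalized expression of the set
#' minus the mean of an expression-matched control set: features are binned
#' by average expression (`n_bins` equal-size bins) and `n_ctrl` control
#' features are drawn from each marker's bin. Phase is G2/M if the G2M score
#' is highest and positive, S if the S score is highest and positive, and
#' G0/G1 otherwise.
#'
#' @param x normalized RNA `scm`.
#' @param s_genes,g2m_genes marker feature ids (non-empty, present in `x`).
#' @param n_bins,n_ctrl binning and control-set size of the scoring scheme.
#' @return tibble: cell_id, score_s, score_g2m, phase.
#' @export
score_cell_cycle <- function(x, s_genes, g2m_genes, n_bins = 25L, n_ctrl = 50L) {
  stopifnot(inherits(x, "scm"), x$modality == "rna")
  if (!length(s_genes) || !length(g2m_genes)) {
    stop("marker lists must be non-empty", call. = FALSE)
  }
  v <- scm_values(x)
  s_genes <- intersect(s_genes, colnames(v))
  g2m_genes <- intersect(g2m_genes, colnames(v))
  if (!length(s_genes) || !length(g2m_genes)) {
    stop("marker lists share no features with the matrix", call. = FALSE)
  }
  avg <- colMeans(v)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  score_one <- function(set) {
    ctrl <- unlist(lapply(set, function(g) {
      pool <- setdiff(colnames(v)[bin == bin[match(g, colnames(v))]], set)
      if (!length(pool)) return(character(0))
      sample(pool, min(n_ctrl, length(pool)), replace = length(pool) < n_ctrl)
    }))
    ctrl_mean <- if (length(ctrl)) rowMeans(v[, ctrl, drop = FALSE]) else 0
    rowMeans(v[, set, drop = FALSE]) - ctrl_mean
  }
  s_score <- score_one(s_genes)
  g2m_score <- score_one(g2m_genes)
  phase <- dplyr::case_when(
    g2m_score > s_score & g2m_score > 0 ~ "G2/M",
    s_score >= g2m_score & s_score > 0 ~ "S",
    .default = "G0/G1"
  )
  tibble::tibble(cell_id = rownames(v), score_s = s_score,
                 score_g2m = g2m_score, phase = phase)
}

#' Effect of imputation on stimulus-associated embedding variance
#'
#' Quantifies how much of the stimulus (response-time) variance the diffusion
#' embedding captures before and after k-NN imputation. The pre-imputation
#' branch fills missing entries with zeros — the effective treatment of
#' missingness in a standard embedding workflow without the imputation step —
#' while the post branch uses the imputed matrix. The statistic is the R^2 of
#' regressing the reference signal on the non-stationary diffusion components
#' (2..m), i.e. the fraction of stimulus variance resolved by the embedding.
#'
#' @param pre normalized protein `scm` with missing mask (not imputed).
#' @param post the matching imputed `scm`.
#' @param reference numeric per-cell signal (e.g. true response time on
#'   synthetic data), aligned by cell id.
#' @param n_neighbors,n_comps diffusion-map parameters.
#' @return tibble: r2_pre, r2_post, gain.
#' @export
imputation_effect <- function(pre, post, reference, n_neighbors = 15L,
                              n_comps = 10L) {
  stopifnot(inherits(pre, "scm"), inherits(post, "scm"))
  zf <- pre
  zf$values[is.na(zf$values)] <- 0
  r2_of <- function(m) {
    dm <- diffusion_map(m, NULL, n_neighbors, n_comps)
    r <- reference[match(dm$cell_ids, names(reference))]
    summary(stats::lm(r ~ dm$psi[, -1]))$r.squared
  }
  ref <- reference
  if (is.null(names(ref))) {
    stopifnot(length(ref) == n_cells(pre))
    names(ref) <- cell_ids(pre)
  }
  reference <- ref
  r2_pre <- r2_of(zf)
  r2_post <- r2_of(post)
  tibble::tibble(r2_pre = r2_pre, r2_post = r2_post, gain = r2_post - r2_pre)
}
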