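#' Pipeline configuration
#'
#' Collects every stage parameter in one place so that each analysis constant
#' lives exactly once: QC thresholds, the marker-set size K = 50, the target
#' sum 1e4, trajectory and integration parameters, and (for simulated runs)
#' the generator configuration.
#'
#' @param simulate generate the inputs with [simulate_experiment()] (default)
#'   instead of reading them from disk.
#' @param generator a [generator_config()] (simulated runs; its seed is
#'   overridden by `seed`).
#' @param rna_mtx_dir,protein_tsv,rna_metadata_tsv,protein_metadata_tsv input
#'   paths for non-simulated runs.
#' @param thresholds a [qc_thresholds()]; `NULL` picks the standard gates,
#'   with the panel-size-dependent feature-count gates rescaled to the
#'   simulated panel for simulated runs.
#' @param K hypoxia marker-set size per modality.
#' @param impute_k neighbors for protein imputation.
#' @param n_neighbors,n_comps diffusion-map graph and spectrum sizes.
#' @param window_fraction,grid_size profile windowing on the common axis.
#' @param onset_threshold fraction-of-final-value rule for onset estimation.
#' @param leiden_resolution,detect_subpop subpopulation screen; detected
#'   candidate-subpopulation cells are excluded from marker ranking and
#'   trajectories.
#' @param s_genes,g2m_genes cell-cycle marker lists for RNA phase scoring
#'   (`NULL` on simulated runs: cycle features peaking in the S / G2M
#'   segments).
#' @param fast_markers,slow_markers anchor features for zone demarcation
#'   (`NULL` on simulated runs: upregulated hypoxia features with the
#'   smallest / largest onset delays).
#' @param target_sum normalization target sum.
#' @param output_dir when set, all stage outputs and a run manifest are
#'   written beneath it (TSV/JSON only).
#' @param seed seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, generator = generator_config(),
                            rna_mtx_dir = NULL, protein_tsv = NULL,
                            rna_metadata_tsv = NULL, protein_metadata_tsv = NULL,
                            thresholds = NULL, K = 50L, impute_k = 5L,
                            n_neighbors = 15L, n_comps = 10L,
                            window_fraction = 0.1, grid_size = 100L,
                            onset_threshold = 0.5,
                            leiden_resolution = 0.25, detect_subpop = TRUE,
                            s_genes = NULL, g2m_genes = NULL,
                            fast_markers = NULL, slow_markers = NULL,
                            target_sum = 1e4, output_dir = NULL, seed = 1L) {
  if (!simulate) {
    paths <- c(rna_mtx_dir, protein_tsv, rna_metadata_tsv, protein_metadata_tsv)
    if (length(paths) < 4 || !all(file.exists(paths))) {
      stop("non-simulated runs need existing rna_mtx_dir, protein_tsv, ",
           "rna_metadata_tsv and protein_metadata_tsv", call. = FALSE)
    }
  }
  if (is.null(thresholds)) {
    thresholds <- if (simulate) {
      qc_thresholds(prot_min_features = max(10L, round(0.25 * generator$n_features)),
                    rna_min_genes = max(10L, round(generator$n_features / 3)),
                    impute_k = impute_k)
    } else {
      qc_thresholds(impute_k = impute_k)
    }
  }
  stopifnot(K > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full integration pipeline
#'
#' Simulate (or load) -> QC filters -> normalization (+ protein k-NN
#' imputation) -> cell-cycle annotation -> subpopulation screen (Leiden,
#' Wilcoxon DE, cross-modality concordance; candidate cells excluded
#' downstream) -> likelihood-ratio marker ranking -> per-modality diffusion
#' pseudotime -> anchor-warp alignment, joint profiles, onset/lag and zones.
#'
#' @param config a [pipeline_config()].
#' @return a list with every stage result plus a `manifest` (parameters,
#'   seed, warnings, output file hashes when `output_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  catch <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(catch(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- inputs ---------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    gen <- config$generator
    gen$seed <- config$seed
    sim <- stage("simulate", simulate_experiment(gen))
    rna <- sim$rna; prot <- sim$prot; truth <- sim$truth
  } else {
    rna <- stage("load_rna", {
      m <- read_rna_mtx(config$rna_mtx_dir)
      ann <- readr::read_tsv(config$rna_metadata_tsv, show_col_types = FALSE)
      list(mat = m, ann = annotate_cells(m, ann))
    })
    prot <- stage("load_protein", {
      m <- read_protein_tsv(config$protein_tsv)
      ann <- readr::read_tsv(config$protein_metadata_tsv, show_col_types = FALSE)
      list(mat = m, ann = annotate_cells(m, ann))
    })
  }

  ## ---- qc + normalization --------------------------------------------
  qc_rna <- stage("qc_rna", filter_cells(rna$mat, rna$ann, config$thresholds))
  qc_prot <- stage("qc_prot", filter_cells(prot$mat, prot$ann, config$thresholds))
  norm_rna <- stage("normalize_rna",
                    normalize_log1p(qc_rna$mat, config$target_sum))
  norm_prot <- stage("normalize_prot",
                     normalize_log1p(qc_prot$mat, config$target_sum))
  imp_prot <- stage("impute_prot", {
    m <- knn_impute(norm_prot, k = config$thresholds$impute_k)
    bad <- attr(m, "unimputable_features")
    if (length(bad)) {
      warning(length(bad), " never-observed protein feature(s) dropped")
      m <- scm_subset(m, features = setdiff(feature_ids(m), bad))
    }
    m
  })

  ## ---- cell-cycle annotation -----------------------------------------
  ann_prot <- stage("phase_prot", assign_phase_from_fucci(qc_prot$ann))
  s_genes <- config$s_genes
  g2m_genes <- config$g2m_genes
  if (config$simulate && (is.null(s_genes) || is.null(g2m_genes))) {
    cyc <- truth$features[truth$features$class == "cycle", ]
    s_genes <- cyc$feature_id[cyc$cycle_phase >= 0.5 & cyc$cycle_phase < 0.8]
    g2m_genes <- cyc$feature_id[cyc$cycle_phase >= 0.8]
  }
  set.seed(config$seed)
  cc <- stage("phase_rna",
              score_cell_cycle(norm_rna, s_genes, g2m_genes))
  ann_rna <- dplyr::left_join(qc_rna$ann,
                              dplyr::select(cc, "cell_id", "phase",
                                            "score_s", "score_g2m"),
                              by = "cell_id")

  ## ---- subpopulation screen ------------------------------------------
  subpop <- NULL
  if (config$detect_subpop) {
    subpop <- stage("subpop", {
      cl_rna <- cluster_cells(norm_rna, config$n_neighbors,
                              config$leiden_resolution, seed = config$seed)
      cl_prot <- cluster_cells(imp_prot, config$n_neighbors,
                               config$leiden_resolution, seed = config$seed)
      grp <- function(cl) ifelse(cl$candidate_subpop, "small", "large")
      de_rna <- de_prot <- NULL
      conc <- NULL
      if (any(cl_rna$candidate_subpop) && any(cl_prot$candidate_subpop)) {
        de_rna <- wilcoxon_de(norm_rna, grp(cl_rna), preset = "subpopulation")
        de_rna <- de_rna[de_rna$group == "small", ]
        de_prot <- wilcoxon_de(imp_prot, grp(cl_prot), preset = "subpopulation")
        de_prot <- de_prot[de_prot$group == "small", ]
        conc <- mutual_de_concordance(de_rna, de_prot)
      }
      list(clusters_rna = cl_rna, clusters_prot = cl_prot,
           composition_rna = composition_table(cl_rna, ann_rna),
           composition_prot = composition_table(cl_prot, ann_prot),
           de_rna = de_rna, de_prot = de_prot, concordance = conc)
    })
    keep_rna <- subpop$clusters_rna$cell_id[!subpop$clusters_rna$candidate_subpop]
    keep_prot <- subpop$clusters_prot$cell_id[!subpop$clusters_prot$candidate_subpop]
    norm_rna <- scm_subset(norm_rna, cells = cell_ids(norm_rna) %in% keep_rna)
    imp_prot <- scm_subset(imp_prot, cells = cell_ids(imp_prot) %in% keep_prot)
    ann_rna <- ann_rna[ann_rna$cell_id %in% keep_rna, ]
    ann_prot <- ann_prot[ann_prot$cell_id %in% keep_prot, ]
  }

  ## ---- marker ranking -------------------------------------------------
  lrt_rna <- stage("markers_rna", lrt_rank_markers(
    norm_rna, phase = ann_rna$phase[match(cell_ids(norm_rna), ann_rna$cell_id)],
    time_point = ann_rna$time_point_h[match(cell_ids(norm_rna), ann_rna$cell_id)],
    K = min(config$K, n_features(norm_rna))))
  lrt_prot <- stage("markers_prot", lrt_rank_markers(
    imp_prot, phase = ann_prot$phase[match(cell_ids(imp_prot), ann_prot$cell_id)],
    time_point = ann_prot$time_point_h[match(cell_ids(imp_prot), ann_prot$cell_id)],
    K = min(config$K, n_features(imp_prot))))

  ## ---- trajectories ---------------------------------------------------
  run_traj <- function(mat, ann, markers) {
    dm <- diffusion_map(mat, markers, n_neighbors = config$n_neighbors,
                        n_comps = min(config$n_comps, n_cells(mat) - 1L))
    root <- choose_root(mat, markers, ann)
    pt <- dpt_pseudotime(dm, root)
    list(diffusion = dm, pt = pseudotemporal_order(pt, ann))
  }
  traj_rna <- stage("trajectory_rna",
                    run_traj(norm_rna, ann_rna, lrt_rna$markers))
  traj_prot <- stage("trajectory_prot",
                     run_traj(imp_prot, ann_prot, lrt_prot$markers))

  ## ---- integration ----------------------------------------------------
  warp <- stage("align", align_axes(traj_rna$pt, traj_prot$pt, ann_rna, ann_prot))
  onset <- stage("onset_lag", estimate_onset_lag(
    traj_rna$pt$summary, traj_prot$pt$summary, config$onset_threshold))
  fast <- config$fast_markers
  slow <- config$slow_markers
  if (config$simulate && (is.null(fast) || is.null(slow))) {
    up <- truth$features[truth$features$class == "hypoxia" &
                           truth$features$direction > 0, ]
    up <- up[order(up$delay_h), ]
    fast <- utils::head(up$feature_id, 3)
    slow <- utils::tail(up$feature_id, 3)
  }
  anchors <- unique(c(fast, slow))
  profiles <- stage("profiles", dplyr::bind_rows(
    feature_profile(norm_rna, warp$coords, intersect(anchors, feature_ids(norm_rna)),
                    config$window_fraction, config$grid_size),
    feature_profile(imp_prot, warp$coords, intersect(anchors, feature_ids(imp_prot)),
                    config$window_fraction, config$grid_size)))
  zones <- stage("zones", demarcate_zones(
    profiles[profiles$modality == "rna", ], fast, slow))

  res <- list(
    rna = list(mat = norm_rna, ann = ann_rna, qc = qc_rna$report),
    prot = list(mat = imp_prot, ann = ann_prot, qc = qc_prot$report),
    truth = truth, subpop = subpop,
    lrt_rna = lrt_rna, lrt_prot = lrt_prot,
    traj_rna = traj_rna, traj_prot = traj_prot,
    warp = warp, onset = onset, profiles = profiles, zones = zones
  )

  manifest <- list(
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      K = config$K, target_sum = config$target_sum,
      impute_k = config$thresholds$impute_k,
      n_neighbors = config$n_neighbors, n_comps = config$n_comps,
      leiden_resolution = config$leiden_resolution,
      window_fraction = config$window_fraction,
      grid_size = config$grid_size, onset_threshold = config$onset_threshold,
      thresholds = unclass(config$thresholds)[
        !vapply(unclass(config$thresholds), is.null, logical(1))],
      root_rna = traj_rna$pt$root, root_prot = traj_prot$pt$root
    ),
    warnings = warnings_log
  )
  if (!is.null(config$output_dir)) {
    manifest$files <- write_pipeline_outputs(res, manifest, config$output_dir)
  }
  res$manifest <- manifest
  res
}

# write TSV/JSON stage outputs and return md5 hashes
write_pipeline_outputs <- function(res, manifest, out_dir) {
  stage_dir <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    p
  }
  qcd <- stage_dir("qc"); mkd <- stage_dir("markers")
  trd <- stage_dir("trajectory"); ind <- stage_dir("integration")
  readr::write_tsv(res$rna$qc, file.path(qcd, "qc_report_rna.tsv"))
  readr::write_tsv(res$prot$qc, file.path(qcd, "qc_report_protein.tsv"))
  readr::write_tsv(res$lrt_rna$table, file.path(mkd, "lrt_rna.tsv"))
  readr::write_tsv(res$lrt_prot$table, file.path(mkd, "lrt_protein.tsv"))
  jsonlite::write_json(list(rna = as.character(res$lrt_rna$markers),
                            protein = as.character(res$lrt_prot$markers)),
                       file.path(mkd, "marker_sets.json"))
  for (m in c("rna", "prot")) {
    pt <- res[[paste0("traj_", m)]]$pt
    readr::write_tsv(tidy(pt), file.path(trd, paste0("pseudotime_", m, ".tsv")))
    jsonlite::write_json(res[[paste0("traj_", m)]]$diffusion$evals,
                         file.path(trd, paste0("eigenvalues_", m, ".json")))
  }
  readr::write_tsv(res$profiles, file.path(ind, "joint_profiles.tsv"))
  readr::write_tsv(res$warp$anchors, file.path(ind, "anchors.tsv"))
  jsonlite::write_json(as.list(res$onset), file.path(ind, "onset_lag.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(res$zones[c("u_pre", "u_onset")],
                       file.path(ind, "zones.json"), auto_unbox = TRUE, na = "null")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  hashes
}
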