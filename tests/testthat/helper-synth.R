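# small generator configuration for fast unit tests
tiny_config <- function(seed = 1L, ...) {
  generator_config(
    n_rna_cells_per_timepoint = 40, n_prot_cells_per_timepoint = 30,
    n_cycle = 10, n_hypoxia = 10, n_housekeeping = 10,
    n_subpop_features = 6, seed = seed, ...
  )
}

# QC thresholds matched to the tiny panel
tiny_thresholds <- function() {
  qc_thresholds(prot_min_features = 10, rna_min_genes = 10)
}

# memoized default-scale pipeline runs shared across acceptance blocks
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(seed, low_noise = FALSE) {
  key <- paste0("s", seed, if (low_noise) "_lo")
  if (is.null(.run_cache[[key]])) {
    gen <- if (low_noise) generator_config(protein_noise_cv = 0.05) else generator_config()
    .run_cache[[key]] <- tryCatch(
      run_pipeline(pipeline_config(seed = seed, generator = gen)),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "failed_run"))
  }
  .run_cache[[key]]
}

# adjusted Rand index (small closed form; oracle for clustering tests)
ari <- function(a, b) {
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(ct))
  si <- sum(comb2(rowSums(ct)))
  sj <- sum(comb2(colSums(ct)))
  n2 <- comb2(sum(ct))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# build an scm quickly from a matrix
mk_scm <- function(v, modality = "rna", transform = "raw") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("c%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("g%03d", seq_len(ncol(v)))
  x <- scm(v, modality, "raw")
  x$transform <- transform
  x
}
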