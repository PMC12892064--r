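#' Configuration for the coupled mRNA/protein simulator
#'
#' Builds the parameter list consumed by [simulate_experiment()]. The defaults
#' describe a desk-scale hypoxia time course on a proliferating FUCCI cell
#' line: six proteome and five transcriptome sampling times inside an 8 h
#' window, per-cell heterogeneous response delays, cell-cycle-periodic
#' features, hypoxia-responsive features with per-feature onset delays, and
#' protein levels produced from the mRNA trajectory by first-order synthesis /
#' degradation kinetics whose nominal lag is `ln(2)/k_deg` (2 h at default
#' `k_deg`).
#'
#' @param n_rna_cells_per_timepoint,n_prot_cells_per_timepoint cells sampled
#'   per time point in each modality.
#' @param timepoints_rna_h,timepoints_prot_h strictly increasing sampling
#'   times (hours since onset of hypoxia).
#' @param n_cycle,n_hypoxia,n_housekeeping feature-panel partition; the total
#'   panel size is their sum.
#' @param hypoxia_amplitude_range interval (natural-log units) for per-feature
#'   hypoxia effect sizes.
#' @param prob_up probability that a hypoxia feature is upregulated.
#' @param cycle_amplitude_range interval for per-feature cell-cycle effect
#'   amplitudes (natural-log units of the von-Mises-shaped bump over cycle
#'   position).
#' @param per_cell_delay_meanlog,per_cell_delay_sdlog lognormal parameters of
#'   the per-cell response delay `delta_i` (hours).
#' @param per_feature_delay_range interval for the per-feature onset delay
#'   `tau_g` (hours).
#' @param activation_steepness_range interval for the logistic activation
#'   steepness `s_g` (hours).
#' @param k_syn,k_deg first-order protein synthesis and degradation rates
#'   (per hour); the generator's nominal transcription-translation lag is
#'   `ln(2)/k_deg`.
#' @param rna_nb_dispersion negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param library_size_meanlog,library_size_sdlog lognormal parameters of the
#'   per-cell RNA library size.
#' @param protein_total_log2_mean,protein_total_log2_sd per-cell total
#'   reporter S/N on the log2 scale (before doublet/failed-well scaling).
#' @param protein_noise_cv multiplicative (lognormal) measurement noise CV on
#'   protein intensities.
#' @param detection_midpoint,detection_slope logistic detection model on the
#'   natural-log intensity: P(observed) = plogis((log I - midpoint) * slope).
#' @param phase_weights sampling weights of the three cycle-phase segments
#'   (G0/G1, S, G2/M); defaults reflect typical phase durations (G2/M the
#'   shortest).
#' @param fucci_green_means,fucci_red_means named per-phase mean reporter
#'   intensities (mAzamiGreen high in G0/G1, mMaroon1 high in S, both
#'   intermediate in G2/M).
#' @param fucci_sdlog lognormal noise of reporter intensities.
#' @param subpop_fraction fraction of cells belonging to a planted
#'   subpopulation distinct from both covariates; 0 disables it.
#' @param subpop_discordant_fraction fraction of subpopulation marker features
#'   whose protein fold-change direction is flipped relative to mRNA.
#' @param subpop_amplitude,n_subpop_features effect size (natural-log units)
#'   and number of housekeeping features carrying the subpopulation signal.
#' @param subpop_abundance_shift baseline log-abundance shift of the
#'   subpopulation marker features in the protein panel (positive: the
#'   subpopulation phenotype lives in abundant machinery, so down-regulated
#'   members stay above the detection limit).
#' @param hypoxia_rna_abundance_shift baseline log-abundance shift of the
#'   hypoxia-responsive features in the RNA panel (negative: stress-response
#'   transcripts are a small mass fraction of the library, as in a full
#'   transcriptome, so their activation does not induce compositional
#'   pseudo-effects on the rest of the panel under target-sum
#'   normalization).
#' @param hypoxia_prot_abundance_shift baseline log-abundance shift of the
#'   hypoxia-responsive features in the protein panel (negative: the hypoxia
#'   signal lives in sparsely quantified proteins under DDA-like detection,
#'   while abundant complete proteins carry the cell-cycle signal — the
#'   regime in which k-NN imputation recovers the stimulus variance).
#' @param doublet_fraction,failed_cell_fraction fractions of protein wells
#'   whose total signal is scaled by 2 (sorted doublet) or 0.3 (failed
#'   measurement), giving the log2-sum-S/N gate true positives to remove.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_rna_cells_per_timepoint = 200,
                             n_prot_cells_per_timepoint = 110,
                             timepoints_rna_h = c(0, 0.75, 2, 4, 8),
                             timepoints_prot_h = c(0, 0.75, 2, 4, 6, 8),
                             n_cycle = 50, n_hypoxia = 50, n_housekeeping = 50,
                             hypoxia_amplitude_range = c(1, 2),
                             prob_up = 0.7,
                             cycle_amplitude_range = c(0.4, 1.2),
                             per_cell_delay_meanlog = log(0.5),
                             per_cell_delay_sdlog = 0.8,
                             per_feature_delay_range = c(0, 2),
                             activation_steepness_range = c(0.25, 1),
                             k_syn = 1, k_deg = log(2) / 2,
                             rna_nb_dispersion = 0.1,
                             library_size_meanlog = log(15000),
                             library_size_sdlog = 0.25,
                             protein_total_log2_mean = 16.9,
                             protein_total_log2_sd = 0.1,
                             protein_noise_cv = 0.2,
                             detection_midpoint = 5.5,
                             detection_slope = 1,
                             phase_weights = c(`G0/G1` = 0.50, S = 0.35, `G2/M` = 0.15),
                             fucci_green_means = c(`G0/G1` = 1500, S = 50, `G2/M` = 500),
                             fucci_red_means = c(`G0/G1` = 50, S = 1500, `G2/M` = 500),
                             fucci_sdlog = 0.3,
                             subpop_fraction = 0.08,
                             subpop_discordant_fraction = 0.3,
                             subpop_amplitude = 1.5,
                             subpop_abundance_shift = 2.5,
                             hypoxia_rna_abundance_shift = -2,
                             hypoxia_prot_abundance_shift = -1.5,
                             n_subpop_features = 30,
                             doublet_fraction = 0.03,
                             failed_cell_fraction = 0.03,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_features <- n_cycle + n_hypoxia + n_housekeeping
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  bad <- function(msg) stop("invalid generator config: ", msg, call. = FALSE)
  if (cfg$n_cycle < 0 || cfg$n_hypoxia < 0 || cfg$n_housekeeping < 0 ||
      cfg$n_cycle + cfg$n_hypoxia + cfg$n_housekeeping != cfg$n_features) {
    bad("feature partition must be non-negative and sum to n_features")
  }
  for (tp in list(cfg$timepoints_rna_h, cfg$timepoints_prot_h)) {
    if (any(tp < 0) || is.unsorted(tp, strictly = TRUE)) {
      bad("timepoints must be non-negative and strictly increasing")
    }
  }
  if (cfg$k_syn <= 0 || cfg$k_deg <= 0) bad("rates must be positive")
  if (cfg$rna_nb_dispersion <= 0) bad("rna_nb_dispersion must be positive")
  if (cfg$detection_slope <= 0) bad("detection_slope must be positive")
  if (cfg$subpop_fraction < 0 || cfg$subpop_fraction >= 1) bad("subpop_fraction in [0,1)")
  if (cfg$subpop_discordant_fraction < 0 || cfg$subpop_discordant_fraction > 1) {
    bad("subpop_discordant_fraction in [0,1]")
  }
  if (cfg$doublet_fraction < 0 || cfg$doublet_fraction >= 1 ||
      cfg$failed_cell_fraction < 0 || cfg$failed_cell_fraction >= 1) {
    bad("artifact fractions in [0,1)")
  }
  if (cfg$n_subpop_features > cfg$n_housekeeping) {
    bad("n_subpop_features cannot exceed n_housekeeping")
  }
  invisible(cfg)
}

# Normalized logistic activation: 0 at elapsed response time e = 0, -> 1.
# e = max(0, t - delta_i); tau shifts the onset, s sets the rise time.
activation_fraction <- function(e, tau, s) {
  base <- stats::plogis(-tau / s)
  val <- (stats::plogis((e - tau) / s) - base) / (1 - base)
  val[val < 0] <- 0
  val
}

#' First-order protein kinetics driven by an mRNA trajectory
#'
#' Solves `dP/dt = k_syn * M(t) - k_deg * P` with steady-state initialisation
#' `P(t0) = k_syn * M(t0) / k_deg`, the mechanism by which the simulator turns
#' an immediate transcriptional response into a lagged proteomic one (half-
#' response lag `ln(2)/k_deg` for a step input).
#'
#' @param mrna_trajectory function of time returning M(t) (vectorized or not).
#' @param k_syn,k_deg synthesis and degradation rates (per hour); `k_deg > 0`.
#' @param t_grid increasing time grid (hours) on which to return P.
#' @return numeric vector of protein abundances along `t_grid`.
#' @examples
#' p <- protein_kinetics(function(t) rep(2, length(t)), 1, 0.5, 0:5)
#' all.equal(p, rep(4, 6)) # steady state
#' @export
protein_kinetics <- function(mrna_trajectory, k_syn, k_deg, t_grid) {
  if (k_deg <= 0) stop("k_deg must be positive", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  m_fun <- function(t) vapply(t, function(ti) mrna_trajectory(ti)[[1]], numeric(1))
  # refine each interval so the midpoint-exponential update stays accurate
  p <- numeric(length(t_grid))
  p[1] <- k_syn * m_fun(t_grid[1]) / k_deg
  for (j in seq_len(length(t_grid) - 1L)) {
    a <- t_grid[j]; b <- t_grid[j + 1L]
    nsub <- max(1L, ceiling((b - a) / min(0.02, 0.05 / k_deg)))
    ts <- seq(a, b, length.out = nsub + 1L)
    cur <- p[j]
    for (s in seq_len(nsub)) {
      mid <- k_syn * m_fun((ts[s] + ts[s + 1L]) / 2) / k_deg
      cur <- mid + (cur - mid) * exp(-k_deg * (ts[s + 1L] - ts[s]))
    }
    p[j + 1L] <- cur
  }
  pmax(p, 0)
}

# vectorized kinetics used by the generator: m_mat is features x (steps + 1)
# of the normalized mRNA multiplier along a uniform grid with spacing dt;
# returns the relative protein multiplier at the final grid point, with
# steady-state initialisation at the first column.
kinetics_relative <- function(m_mat, dt, k_deg) {
  p <- m_mat[, 1L]
  ns <- ncol(m_mat) - 1L
  if (ns < 1L) return(p)
  decay <- exp(-k_deg * dt)
  for (s in seq_len(ns)) {
    mid <- (m_mat[, s] + m_mat[, s + 1L]) / 2
    p <- mid + (p - mid) * decay
  }
  p
}

#' Abundance-biased detection model
#'
#' Logistic model of DDA-like missingness: more abundant proteins are more
#' likely to be observed. `detection_prob()` returns the detection
#' probability; `detection_model()` draws observed/missing indicators.
#'
#' @param log_abundance natural-log abundance (vector).
#' @param midpoint log-abundance at which detection probability is 0.5.
#' @param slope positive steepness; large values approach a step function.
#' @return `detection_prob()`: probabilities; `detection_model()`: logical
#'   vector, `TRUE` = observed.
#' @export
detection_prob <- function(log_abundance, midpoint, slope) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  stats::plogis((log_abundance - midpoint) * slope)
}

#' @rdname detection_prob
#' @export
detection_model <- function(log_abundance, midpoint, slope) {
  p <- detection_prob(log_abundance, midpoint, slope)
  stats::runif(length(p)) < p
}

# duration-weighted cell-cycle position: piecewise-uniform density over the
# fixed phase segments [0,.5), [.5,.8), [.8,1) with the configured weights.
sample_theta <- function(n, weights) {
  seg <- sample.int(3L, n, replace = TRUE, prob = weights)
  lo <- c(0, 0.5, 0.8)[seg]
  hi <- c(0.5, 0.8, 1)[seg]
  stats::runif(n, lo, hi)
}

phase_from_theta <- function(theta) {
  cut(theta, breaks = c(0, 0.5, 0.8, 1), right = FALSE,
      labels = c("G0/G1", "S", "G2/M")) |> as.character()
}

# shared per-cell latent state for one modality
draw_cells <- function(cfg, n_per_tp, timepoints, prefix) {
  n <- n_per_tp * length(timepoints)
  tibble::tibble(
    cell_id = sprintf("%s%04d", prefix, seq_len(n)),
    time_point_h = rep(timepoints, each = n_per_tp),
    theta = sample_theta(n, cfg$phase_weights),
    delta_h = stats::rlnorm(n, cfg$per_cell_delay_meanlog, cfg$per_cell_delay_sdlog),
    subpop = stats::runif(n) < cfg$subpop_fraction
  ) |>
    dplyr::mutate(
      phase_true = phase_from_theta(.data$theta),
      response_time_h = pmax(0, .data$time_point_h - .data$delta_h)
    )
}

# cells x features matrix of log-scale cell-cycle effects
static_log_effects <- function(cells, feats) {
  cyc <- outer(cells$theta, feats$cycle_phase, function(th, ph) cos(2 * pi * (th - ph)))
  sweep(cyc, 2, feats$cycle_amplitude, `*`)
}

# multiply the planted subpopulation effect into a rate/abundance matrix,
# rescaled per cell so the total mass of the subpop marker set is conserved:
# the effect redistributes output among the markers instead of inflating the
# cell total, so target-sum normalization induces no passenger fold changes
# in the rest of the panel
apply_subpop_effect <- function(mat, cells, feats, direction_col) {
  sp <- which(feats$subpop_amplitude > 0)
  ci <- which(cells$subpop)
  if (!length(sp) || !length(ci)) return(mat)
  mult <- exp(feats$subpop_amplitude[sp] * feats[[direction_col]][sp])
  base <- mat[ci, sp, drop = FALSE]
  eff <- sweep(base, 2, mult, `*`)
  scale <- rowSums(base) / rowSums(eff)
  mat[ci, sp] <- eff * scale
  mat
}

#' Simulate an unpaired single-cell RNA + protein hypoxia experiment
#'
#' Draws shared latent cell states (duration-weighted cell-cycle position,
#' lognormal per-cell response delay) and a feature panel partitioned into
#' cycle-periodic, hypoxia-responsive and housekeeping features, then emits:
#' an RNA counts matrix (negative binomial, lognormal library sizes, no
#' missing entries), a protein reporter-S/N matrix (first-order-kinetics
#' lagged relative to the transcript signal, multiplicative noise,
#' abundance-biased logistic missingness, FUCCI reporter intensities,
#' planted doublets/failed wells), and the full ground truth.
#'
#' @param config a [generator_config()].
#' @return list with elements `rna` (`scm` + `$ann` tibble), `prot`
#'   (`scm` + `$ann`), and `truth` (list: `cells_rna`, `cells_prot`,
#'   `features`, `true_lag_h`, `config`).
#' @export
simulate_experiment <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ## ---- feature panel --------------------------------------------------
  nf <- cfg$n_features
  classes <- rep(c("cycle", "hypoxia", "housekeeping"),
                 times = c(cfg$n_cycle, cfg$n_hypoxia, cfg$n_housekeeping))
  feats <- tibble::tibble(
    feature_id = sprintf("GENE%03d", seq_len(nf)),
    class = classes,
    base_log_rna = stats::rnorm(nf, 0, 1.2),
    base_log_prot = stats::rnorm(nf, 0, 1.2),
    cycle_phase = stats::runif(nf),
    cycle_amplitude = ifelse(classes == "cycle",
                             stats::runif(nf, cfg$cycle_amplitude_range[1],
                                          cfg$cycle_amplitude_range[2]), 0),
    direction = ifelse(classes == "hypoxia",
                       ifelse(stats::runif(nf) < cfg$prob_up, 1, -1), 0),
    amplitude = ifelse(classes == "hypoxia",
                       stats::runif(nf, cfg$hypoxia_amplitude_range[1],
                                    cfg$hypoxia_amplitude_range[2]), 0),
    delay_h = ifelse(classes == "hypoxia",
                     stats::runif(nf, cfg$per_feature_delay_range[1],
                                  cfg$per_feature_delay_range[2]), 0),
    steepness_h = ifelse(classes == "hypoxia",
                         stats::runif(nf, cfg$activation_steepness_range[1],
                                      cfg$activation_steepness_range[2]), 1)
  )
  feats$base_log_rna[feats$class == "hypoxia"] <-
    feats$base_log_rna[feats$class == "hypoxia"] + cfg$hypoxia_rna_abundance_shift
  feats$base_log_prot[feats$class == "hypoxia"] <-
    feats$base_log_prot[feats$class == "hypoxia"] + cfg$hypoxia_prot_abundance_shift
  feats$subpop_amplitude <- 0
  feats$subpop_dir_rna <- 0
  feats$subpop_dir_prot <- 0
  if (cfg$subpop_fraction > 0 && cfg$n_subpop_features > 0) {
    hk <- which(feats$class == "housekeeping")
    idx <- hk[seq_len(cfg$n_subpop_features)]
    feats$subpop_amplitude[idx] <- cfg$subpop_amplitude
    feats$base_log_prot[idx] <- feats$base_log_prot[idx] + cfg$subpop_abundance_shift
    dir_rna <- sample(c(-1, 1), length(idx), replace = TRUE)
    flip <- stats::runif(length(idx)) < cfg$subpop_discordant_fraction
    feats$subpop_dir_rna[idx] <- dir_rna
    feats$subpop_dir_prot[idx] <- ifelse(flip, -dir_rna, dir_rna)
  }

  ## ---- RNA ------------------------------------------------------------
  cells_rna <- draw_cells(cfg, cfg$n_rna_cells_per_timepoint,
                          cfg$timepoints_rna_h, "RNA")
  nr <- nrow(cells_rna)
  hyp <- feats$class == "hypoxia"
  log_eff_rna <- static_log_effects(cells_rna, feats)
  # hypoxia activation at the cell's elapsed response time
  act <- matrix(0, nr, nf)
  if (any(hyp)) {
    e <- cells_rna$response_time_h
    for (g in which(hyp)) {
      act[, g] <- feats$direction[g] * feats$amplitude[g] *
        activation_fraction(e, feats$delay_h[g], feats$steepness_h[g])
    }
  }
  rate <- exp(sweep(log_eff_rna + act, 2, feats$base_log_rna, `+`))
  rate <- apply_subpop_effect(rate, cells_rna, feats, "subpop_dir_rna")
  p <- rate / rowSums(rate)
  lib <- stats::rlnorm(nr, cfg$library_size_meanlog, cfg$library_size_sdlog)
  mu <- p * lib
  counts <- matrix(stats::rnbinom(nr * nf, mu = as.vector(mu),
                                  size = 1 / cfg$rna_nb_dispersion),
                   nr, nf, dimnames = list(cells_rna$cell_id, feats$feature_id))
  storage.mode(counts) <- "double"
  rna <- scm(counts, "rna")
  cells_rna$library_size <- lib

  ## ---- protein --------------------------------------------------------
  cells_prot <- draw_cells(cfg, cfg$n_prot_cells_per_timepoint,
                           cfg$timepoints_prot_h, "PROT")
  np <- nrow(cells_prot)
  n_art <- ceiling((cfg$doublet_fraction + cfg$failed_cell_fraction) * np)
  art_idx <- if (n_art > 0) sample.int(np, n_art) else integer(0)
  n_doub <- round(cfg$doublet_fraction * np)
  cells_prot$doublet <- FALSE
  cells_prot$failed <- FALSE
  cells_prot$doublet[art_idx[seq_len(n_doub)]] <- TRUE
  cells_prot$failed[setdiff(art_idx, art_idx[seq_len(n_doub)])] <- TRUE

  log_eff_prot <- static_log_effects(cells_prot, feats)
  # kinetics-lagged hypoxia effect per cell x hypoxia feature: first-order
  # relaxation of log protein abundance toward the log mRNA effect, so the
  # nominal half-response lag ln(2)/k_deg holds on the (analysis) log scale
  # independently of the effect amplitude
  kin <- matrix(0, np, sum(hyp))
  if (any(hyp)) {
    dt <- 0.05
    a <- feats$direction[hyp] * feats$amplitude[hyp]
    tau <- feats$delay_h[hyp]
    s <- feats$steepness_h[hyp]
    for (i in seq_len(np)) {
      ti <- cells_prot$time_point_h[i]
      if (ti <= 0) next
      tg <- seq(0, ti, length.out = ceiling(ti / dt) + 1L)
      e <- matrix(pmax(0, tg - cells_prot$delta_h[i]),
                  nrow = length(tau), ncol = length(tg), byrow = TRUE)
      # features x grid log-scale activation (tau, s recycle down columns)
      m <- a * activation_fraction(e, tau, s)
      kin[i, ] <- kinetics_relative(m, tg[2] - tg[1], cfg$k_deg)
    }
  }
  abun <- exp(sweep(log_eff_prot, 2, feats$base_log_prot, `+`))
  abun[, hyp] <- abun[, hyp] * exp(kin)
  abun <- apply_subpop_effect(abun, cells_prot, feats, "subpop_dir_prot")
  # per-cell total reporter S/N, with doublet/failed scaling
  total <- 2^stats::rnorm(np, cfg$protein_total_log2_mean, cfg$protein_total_log2_sd)
  total <- total * ifelse(cells_prot$doublet, 2, ifelse(cells_prot$failed, 0.3, 1))
  intens <- abun / rowSums(abun) * total
  # multiplicative lognormal noise with unit mean
  sdl <- sqrt(log(1 + cfg$protein_noise_cv^2))
  intens <- intens * matrix(stats::rlnorm(np * nf, -sdl^2 / 2, sdl), np, nf)
  # abundance-biased detection
  observed <- matrix(detection_model(as.vector(log(intens)),
                                     cfg$detection_midpoint, cfg$detection_slope),
                     np, nf)
  intens[!observed] <- NA_real_
  dimnames(intens) <- list(cells_prot$cell_id, feats$feature_id)
  prot <- scm(intens, "protein")

  # FUCCI reporters
  gmean <- cfg$fucci_green_means[cells_prot$phase_true]
  rmean <- cfg$fucci_red_means[cells_prot$phase_true]
  cells_prot$fucci_green <- stats::rlnorm(np, log(gmean), cfg$fucci_sdlog)
  cells_prot$fucci_red <- stats::rlnorm(np, log(rmean), cfg$fucci_sdlog)

  ann_rna <- tibble::tibble(cell_id = cells_rna$cell_id,
                            time_point_h = cells_rna$time_point_h)
  ann_prot <- tibble::tibble(cell_id = cells_prot$cell_id,
                             time_point_h = cells_prot$time_point_h,
                             fucci_green = cells_prot$fucci_green,
                             fucci_red = cells_prot$fucci_red)

  list(
    rna = list(mat = rna, ann = annotate_cells(rna, ann_rna)),
    prot = list(mat = prot, ann = annotate_cells(prot, ann_prot)),
    truth = list(cells_rna = cells_rna, cells_prot = cells_prot,
                 features = feats, true_lag_h = log(2) / cfg$k_deg,
                 config = cfg)
  )
}
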