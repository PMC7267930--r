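# Synthetic-cohort generator: parcellated BOLD-like time series with planted
# time-varying modular structure and a phenotype tied to the planted
# stability of each subject's network.

#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort of subjects whose node time series follow a latent
#' block-covariance model: nodes within a planted module share a module
#' factor, all nodes share a global factor, and the between-module coupling
#' is modulated over time by a slow sinusoid. The amplitude of that sinusoid
#' is the subject's planted stability parameter: a larger amplitude produces
#' larger fluctuations of window-wise modularity downstream. The phenotype
#' (an IQ-like score, mean 100, SD-scale set by the slope and noise) is a
#' linear function of the planted amplitude plus Gaussian noise.
#'
#' @param n_subjects number of subjects (>= 3 for cohort generation).
#' @param n_nodes number of nodes per subject (default 114, matching a
#'   114-region cortical parcellation).
#' @param n_timepoints scan length in volumes (default 884).
#' @param tr sampling interval in seconds (default 0.645).
#' @param n_modules number of planted modules (>= 1; >= 2 for a modular
#'   cohort). With 114 nodes and 7 modules the planted blocks coincide with
#'   the canonical seven networks of [make_node_labeling()], mirrored across
#'   hemispheres.
#' @param base_within_cov within-module correlation magnitude in (0, 1).
#' @param base_between_cov baseline between-module correlation in
#'   `[0, base_within_cov)`.
#' @param stability_range length-2 non-negative numeric: each subject's
#'   planted modulation amplitude is drawn uniformly from this interval.
#' @param phenotype_slope phenotype change (IQ points) per unit of planted
#'   amplitude; its sign sets the direction of the planted
#'   phenotype-stability relation.
#' @param noise_sd SD of white observation noise added to the unit-variance
#'   latent signal.
#' @param phenotype_noise_sd SD (IQ points) of the Gaussian noise on the
#'   phenotype.
#' @param modulation_period period of the coupling sinusoid in time points;
#'   kept slow relative to the default 156-point analysis window.
#' @param ar_coef AR(1) smoothing coefficient applied to every node series to
#'   mimic BOLD temporal autocorrelation (0 disables smoothing).
#' @param fd_phenotype_cor target correlation between mean framewise
#'   displacement and the phenotype (0 = independent; nonzero values allow
#'   confound testing).
#' @param seed master seed; identical configurations generate bit-identical
#'   cohorts.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_subjects = 20L,
                              n_nodes = 114L,
                              n_timepoints = 884L,
                              tr = 0.645,
                              n_modules = 7L,
                              base_within_cov = 0.6,
                              base_between_cov = 0.1,
                              stability_range = c(0, 0.4),
                              phenotype_slope = -60,
                              noise_sd = 0.5,
                              phenotype_noise_sd = 5,
                              modulation_period = 400L,
                              ar_coef = 0.3,
                              fd_phenotype_cor = 0,
                              seed = 1L) {
  if (!is_count(n_subjects, 1) || !is_count(n_nodes, 2) ||
      !is_count(n_timepoints, 2) || !is_count(n_modules, 1)) {
    stop_dynmod("n_subjects, n_nodes, n_timepoints and n_modules must be positive integers (n_nodes >= 2)",
                class = "dynmod_invalid_config")
  }
  if (!is_number(tr) || tr <= 0) {
    stop_dynmod("tr must be a positive number of seconds", class = "dynmod_invalid_config")
  }
  if (!is_number(base_within_cov) || base_within_cov <= 0 || base_within_cov >= 1) {
    stop_dynmod("base_within_cov must lie in (0, 1)", class = "dynmod_invalid_config")
  }
  if (!is_number(base_between_cov) || base_between_cov < 0 ||
      base_between_cov >= base_within_cov) {
    stop_dynmod("base_between_cov must lie in [0, base_within_cov)",
                class = "dynmod_invalid_config")
  }
  if (length(stability_range) != 2L || any(!is.finite(stability_range)) ||
      any(stability_range < 0) || stability_range[2] < stability_range[1]) {
    stop_dynmod("stability_range must be a non-decreasing pair of non-negative reals",
                class = "dynmod_invalid_config")
  }
  if (!is_number(noise_sd) || noise_sd < 0 ||
      !is_number(phenotype_noise_sd) || phenotype_noise_sd < 0) {
    stop_dynmod("noise_sd and phenotype_noise_sd must be non-negative",
                class = "dynmod_invalid_config")
  }
  if (!is_count(modulation_period, 2)) {
    stop_dynmod("modulation_period must be an integer >= 2", class = "dynmod_invalid_config")
  }
  if (!is_number(ar_coef) || abs(ar_coef) >= 1) {
    stop_dynmod("ar_coef must lie in (-1, 1)", class = "dynmod_invalid_config")
  }
  if (!is_number(fd_phenotype_cor) || abs(fd_phenotype_cor) > 1) {
    stop_dynmod("fd_phenotype_cor must lie in [-1, 1]", class = "dynmod_invalid_config")
  }
  if (n_modules > n_nodes) {
    stop_dynmod("n_modules cannot exceed n_nodes", class = "dynmod_invalid_config")
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints), tr = tr,
    n_modules = as.integer(n_modules),
    base_within_cov = base_within_cov, base_between_cov = base_between_cov,
    stability_range = as.numeric(stability_range),
    phenotype_slope = phenotype_slope, noise_sd = noise_sd,
    phenotype_noise_sd = phenotype_noise_sd,
    modulation_period = as.integer(modulation_period),
    ar_coef = ar_coef, fd_phenotype_cor = fd_phenotype_cor,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

node_id_labels <- function(n_nodes) {
  sprintf("n%03d", seq_len(n_nodes))
}

#' Planted module labels for a configuration
#'
#' With 114 nodes and 7 modules the planted blocks are the canonical seven
#' networks (both hemispheres of a network share one module); otherwise nodes
#' are split into `n_modules` contiguous, near-equal blocks.
#'
#' @param config a [simulation_config()].
#' @return integer vector of module ids (1-based), one per node.
#' @export
planted_modules <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_modules == 1L) {
    return(rep(1L, config$n_nodes))
  }
  if (config$n_nodes == 114L && config$n_modules == 7L) {
    lab <- make_node_labeling(114L)
    return(as.integer(factor(lab$network_7, levels = yeo7_networks())))
  }
  as.integer(cut(seq_len(config$n_nodes), breaks = config$n_modules, labels = FALSE))
}

subject_amplitude <- function(config, subject_index) {
  set.seed(derive_seed(config$seed, subject_index))
  runif(1, config$stability_range[1], config$stability_range[2])
}

#' Generate one subject's parcellated time series
#'
#' Draws a time-by-node matrix from the latent block-covariance model of the
#' configuration. At time t the correlation between nodes of different
#' modules is `base_between_cov + a * (1 + sin(2*pi*t/period + phi)) / 2`
#' where `a` is the subject's planted amplitude and `phi` a subject-random
#' phase; within-module correlation is `base_within_cov` throughout. White
#' observation noise and optional AR(1) smoothing are applied last. The draw
#' is fully determined by `(config$seed, subject_index)`.
#'
#' @param config a [simulation_config()].
#' @param subject_index subject number in `1:n_subjects`.
#' @return a list with `series` (a `parcellated_ts`) and `truth` (planted
#'   module labels, amplitude, phase, and the per-timepoint between-module
#'   coupling level `coupling`).
#' @export
generate_subject_timeseries <- function(config, subject_index) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(subject_index) || subject_index > config$n_subjects) {
    stop_dynmod("subject_index must be in 1:n_subjects", class = "dynmod_invalid_config")
  }
  n_t <- config$n_timepoints
  n_n <- config$n_nodes
  modules <- planted_modules(config)
  amp <- subject_amplitude(config, subject_index)

  set.seed(derive_seed(config$seed, subject_index))
  runif(1) # amplitude draw consumed first, identical stream as subject_amplitude
  phase <- runif(1, 0, 2 * pi)
  t_idx <- seq_len(n_t)
  coupling <- config$base_between_cov +
    amp * (1 + sin(2 * pi * t_idx / config$modulation_period + phase)) / 2
  coupling <- clip(coupling, 0, config$base_within_cov - 0.05)

  w <- config$base_within_cov
  g <- rnorm(n_t)                                   # global factor
  f <- matrix(rnorm(n_t * config$n_modules), n_t)   # module factors
  eps <- matrix(rnorm(n_t * n_n), n_t)              # node-unique signal
  sb <- sqrt(coupling)
  sw <- sqrt(w - coupling)
  y <- sb * g + sw * f[, modules, drop = FALSE] + sqrt(1 - w) * eps
  if (config$noise_sd > 0) {
    y <- y + config$noise_sd * matrix(rnorm(n_t * n_n), n_t)
  }
  if (config$ar_coef != 0) {
    y <- apply(y, 2, function(col) {
      as.numeric(stats::filter(col, config$ar_coef, method = "recursive"))
    })
  }
  ids <- node_id_labels(n_n)
  colnames(y) <- ids
  series <- parcellated_ts(
    subject_id = sprintf("sub%04d", subject_index),
    data = y, tr = config$tr, node_ids = ids
  )
  list(
    series = series,
    truth = list(
      subject_id = series$subject_id,
      modules = modules, amplitude = amp, phase = phase, coupling = coupling
    )
  )
}

#' Generate a full synthetic cohort
#'
#' Generates every subject's time series plus a phenotype table. The
#' phenotype is `100 + phenotype_slope * (amplitude - midrange) + noise`,
#' clipped to the conventional IQ range `[55, 145]`. Covariates (age, sex,
#' handedness, mean framewise displacement) are drawn independently of the
#' phenotype unless `fd_phenotype_cor` is nonzero, in which case mean FD is
#' constructed to correlate with the phenotype at approximately that level.
#'
#' @param config a [simulation_config()] with `n_subjects >= 3`.
#' @return a list of class `synthetic_cohort` with elements `series` (list of
#'   `parcellated_ts`), `phenotype` (data.frame), `truth` (per-subject ground
#'   truth), `labeling` (a [make_node_labeling()] table when the planted
#'   blocks follow the canonical networks, otherwise a synthetic labeling
#'   over the planted blocks), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_subjects < 3L) {
    stop_dynmod("a cohort needs at least 3 subjects", class = "dynmod_invalid_config")
  }
  subs <- lapply(seq_len(config$n_subjects), function(i) {
    generate_subject_timeseries(config, i)
  })
  series <- lapply(subs, `[[`, "series")
  truth <- lapply(subs, `[[`, "truth")
  amp <- vapply(truth, `[[`, numeric(1), "amplitude")

  set.seed(derive_seed(config$seed, 1e6))
  n <- config$n_subjects
  mid <- mean(config$stability_range)
  fsiq_raw <- 100 + config$phenotype_slope * (amp - mid) +
    rnorm(n, 0, config$phenotype_noise_sd)
  fsiq <- clip(fsiq_raw, 55, 145)
  age <- round(runif(n, 18, 85), 1)
  sex <- rbinom(n, 1, 0.5)
  handedness <- rbinom(n, 1, 0.88)
  if (config$fd_phenotype_cor != 0) {
    r <- config$fd_phenotype_cor
    z_ph <- as.numeric(scale(fsiq_raw))
    fd_z <- r * z_ph + sqrt(1 - r^2) * rnorm(n)
  } else {
    fd_z <- rnorm(n)
  }
  mean_fd <- clip(0.12 + 0.04 * fd_z, 0.01, 0.6)

  phenotype <- data.frame(
    subject_id = vapply(series, `[[`, character(1), "subject_id"),
    fsiq = fsiq, age = age, sex = sex, handedness = handedness,
    mean_fd = mean_fd, stringsAsFactors = FALSE
  )
  labeling <- if (config$n_nodes == 114L) {
    make_node_labeling(114L)
  } else {
    synthetic_block_labeling(config)
  }
  structure(
    list(series = series, phenotype = phenotype, truth = truth,
         labeling = labeling, config = config),
    class = "synthetic_cohort"
  )
}

# labeling for non-114-node configs: planted blocks mapped onto the 7-network
# vocabulary (recycled), single LH hemisphere; enough structure for the
# aggregation code paths to run on toy cohorts.
synthetic_block_labeling <- function(config) {
  modules <- planted_modules(config)
  nets <- yeo7_networks()
  net7 <- nets[((modules - 1L) %% 7L) + 1L]
  data.frame(
    node_id = node_id_labels(config$n_nodes),
    network_7 = net7,
    network_17 = paste0(net7, ((modules - 1L) %/% 7L) + 1L),
    hemisphere = "LH",
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes one TSV per subject (`<subject_id>.tsv`), the phenotype as
#' `phenotype.csv`, the node labeling as `labeling.tsv`, and the ground truth
#' (planted modules, amplitudes, phenotype construction) as
#' `ground_truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$series) {
    write_timeseries(s, file.path(dir, paste0(s$subject_id, ".tsv")))
  }
  write_phenotype(cohort$phenotype, file.path(dir, "phenotype.csv"))
  write_node_labeling(cohort$labeling, file.path(dir, "labeling.tsv"))
  gt <- lapply(cohort$truth, function(tr) {
    list(subject_id = tr$subject_id, amplitude = tr$amplitude,
         phase = tr$phase, modules = tr$modules)
  })
  jsonlite::write_json(
    list(config = unclass(cohort$config), subjects = gt),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
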