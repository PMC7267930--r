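# End-to-end orchestration: simulate/load -> windowed connectivity ->
# resolution selection -> modularity dynamics -> coclassification ->
# association statistics, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles every stage parameter with a master seed. Inputs are either a
#' [simulation_config()] (`simulation =`) or paths to on-disk data
#' (`timeseries_paths`, `labeling_path`, `phenotype_path`).
#'
#' @param simulation a [simulation_config()], or `NULL` when reading data
#'   from disk.
#' @param timeseries_paths character vector of per-subject TSV paths
#'   (ignored when `simulation` is given).
#' @param labeling_path node labeling TSV path.
#' @param phenotype_path phenotype CSV path (`NULL` skips the statistics
#'   stage).
#' @param tr sampling interval for data read from disk.
#' @param window a [window_spec()].
#' @param gamma `"auto"` (per-subject selection against the 17-network
#'   reference) or a fixed numeric resolution.
#' @param grid resolution grid for `"auto"` selection.
#' @param n_runs Louvain restarts per window matrix.
#' @param n_runs_select Louvain restarts per gamma during selection.
#' @param variant quality-function variant, see [modularity_q()].
#' @param state_fraction threshold fraction for state detection.
#' @param sweep_fractions fractions for the threshold sensitivity sweep
#'   (`NULL` skips the sweep).
#' @param covariates covariate columns for the association battery.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            timeseries_paths = NULL,
                            labeling_path = NULL,
                            phenotype_path = NULL,
                            tr = 0.645,
                            window = window_spec(),
                            gamma = "auto",
                            grid = gamma_grid(),
                            n_runs = 100L,
                            n_runs_select = 100L,
                            variant = "signed",
                            state_fraction = 0.5,
                            sweep_fractions = NULL,
                            covariates = c("age", "sex", "handedness", "mean_fd"),
                            seed = 1L) {
  if (is.null(simulation) && is.null(timeseries_paths)) {
    stop_dynmod("either a simulation config or time-series paths are required",
                class = "dynmod_invalid_config")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(inherits(window, "window_spec"))
  if (!identical(gamma, "auto") && !(is_number(gamma) && gamma > 0)) {
    stop_dynmod("gamma must be \"auto\" or a positive number",
                class = "dynmod_invalid_config")
  }
  structure(
    list(simulation = simulation, timeseries_paths = timeseries_paths,
         labeling_path = labeling_path, phenotype_path = phenotype_path,
         tr = tr, window = window, gamma = gamma, grid = grid,
         n_runs = as.integer(n_runs), n_runs_select = as.integer(n_runs_select),
         variant = match.arg(variant, QUALITY_VARIANTS),
         state_fraction = state_fraction, sweep_fractions = sweep_fractions,
         covariates = covariates, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Compute all dynamic-modularity measures for a cohort
#'
#' Per subject: sliding-window connectivity, resolution selection (optional),
#' window-wise modularity trace, SD(Q), state counts under the individual
#' convention, coclassification stability matrix and its 28 network scores.
#' After all subjects: the group mean Q and state counts under the group
#' convention.
#'
#' @param cohort a `dynmod_cohort` (see [align_cohort()]) or
#'   `synthetic_cohort`.
#' @param config a [pipeline_config()].
#' @param keep_stacks keep the per-subject connectivity stacks in the result
#'   (memory-heavy; needed for [state_profiles()]).
#' @param progress print one line per subject.
#' @return list of class `cohort_measures`: `measures` (data.frame),
#'   `network_scores` (subject x 28 matrix), `traces`, `state_reports_ind`,
#'   `group_mean_q`, `gammas`, and optionally `stacks`.
#' @export
compute_cohort_measures <- function(cohort, config = pipeline_config(simulation = simulation_config()),
                                    keep_stacks = FALSE, progress = FALSE) {
  if (inherits(cohort, "synthetic_cohort")) {
    cohort <- align_cohort(cohort$series, cohort$labeling, cohort$phenotype)
  }
  stopifnot(inherits(cohort, "dynmod_cohort"), inherits(config, "pipeline_config"))
  n_sub <- length(cohort$series)
  ref17 <- cohort$labeling$network_17
  traces <- vector("list", n_sub)
  stacks <- if (keep_stacks) vector("list", n_sub) else NULL
  gammas <- numeric(n_sub)
  net_scores <- NULL
  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- cohort$series[[i]]
    stack <- connectivity_stack(s, config$window)
    if (identical(config$gamma, "auto")) {
      sel <- select_gamma(static_connectivity(s), grid = config$grid,
                          reference = ref17, n_runs = config$n_runs_select,
                          base_seed = derive_seed(config$seed, 2L * i),
                          variant = config$variant)
      gammas[i] <- sel$gamma_star
    } else {
      gammas[i] <- config$gamma
    }
    tr <- q_trace(stack, gamma = gammas[i], n_runs = config$n_runs,
                  base_seed = derive_seed(config$seed, 2L * i + 1L),
                  variant = config$variant)
    traces[[i]] <- tr
    if (keep_stacks) stacks[[i]] <- stack
    co <- stability_matrix(tr$partitions)
    ns <- network_stability(co, cohort$labeling)
    if (is.null(net_scores)) {
      net_scores <- matrix(NA_real_, n_sub, length(ns),
                           dimnames = list(character(n_sub), names(ns)))
    }
    net_scores[i, ] <- ns
    rownames(net_scores)[i] <- s$subject_id
    st <- detect_states(tr, "individual", fraction = config$state_fraction)
    rows[[i]] <- data.frame(
      subject_id = s$subject_id, gamma = gammas[i],
      sd_q = sd_q(tr), mean_q = tr$mean_q,
      n_high_ind = st$n_high, n_low_ind = st$n_low,
      stringsAsFactors = FALSE
    )
    if (progress) {
      message(sprintf("[%d/%d] %s: gamma = %.2f, SD(Q) = %.4f",
                      i, n_sub, s$subject_id, gammas[i], rows[[i]]$sd_q))
    }
  }
  measures <- do.call(rbind, rows)
  gm <- group_mean_q(traces)
  grp <- lapply(traces, detect_states, convention = "group",
                reference_mean = gm, fraction = config$state_fraction)
  measures$n_high_grp <- vapply(grp, `[[`, integer(1), "n_high")
  measures$n_low_grp <- vapply(grp, `[[`, integer(1), "n_low")
  rownames(measures) <- NULL
  out <- list(measures = measures, network_scores = net_scores,
              traces = traces,
              state_reports_ind = lapply(traces, detect_states,
                                         convention = "individual",
                                         fraction = config$state_fraction),
              group_mean_q = gm, gammas = gammas)
  if (keep_stacks) out$stacks <- stacks
  class(out) <- "cohort_measures"
  out
}

#' Run the complete pipeline and write all outputs
#'
#' Simulates or loads the cohort, computes all measures, runs the
#' association battery (when a phenotype is available), optionally runs the
#' threshold sensitivity sweep, and writes every table plus a JSON manifest
#' (configuration, package version, seed, per-stage runtimes) to `out_dir`.
#' Re-running with the same configuration and seed reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param keep_stacks see [compute_cohort_measures()].
#' @return list of class `pipeline_result`: `measures` (a `cohort_measures`),
#'   `report` (an `association_report` or `NULL`), `sweep`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, keep_stacks = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  cohort <- tick("load", {
    if (!is.null(config$simulation)) {
      syn <- generate_cohort(config$simulation)
      align_cohort(syn$series, syn$labeling, syn$phenotype)
    } else {
      series <- lapply(config$timeseries_paths, read_timeseries, tr = config$tr)
      labeling <- read_node_labeling(config$labeling_path)
      phenotype <- if (!is.null(config$phenotype_path)) {
        read_phenotype(config$phenotype_path)
      }
      align_cohort(series, labeling, phenotype)
    }
  })

  mm <- tick("measures", compute_cohort_measures(cohort, config, keep_stacks = keep_stacks))

  report <- NULL
  if (!is.null(cohort$phenotype)) {
    report <- tick("stats", run_association_suite(mm$measures, cohort$phenotype,
                                                  network_scores = mm$network_scores,
                                                  covariates = config$covariates))
  } else {
    warning("no phenotype available: statistics stage skipped")
  }

  sweep <- NULL
  if (!is.null(config$sweep_fractions)) {
    sweep <- tick("sweep", threshold_sweep(mm$traces, "individual",
                                           fractions = config$sweep_fractions))
  }

  tick("write", {
    write.table(mm$measures, file.path(out_dir, "measures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(mm$network_scores, file.path(out_dir, "network_stability.tsv"))
    if (!is.null(report)) {
      write.table(report$correlations, file.path(out_dir, "correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(report$network)) {
        write.table(report$network, file.path(out_dir, "network_associations.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(report$contrasts)) {
        write.table(report$contrasts, file.path(out_dir, "state_contrasts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(sweep)) {
      write.table(sweep, file.path(out_dir, "threshold_sweep.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(NULL)
  })

  manifest <- list(
    package = "dynmod",
    version = as.character(utils::packageVersion("dynmod")),
    seed = config$seed,
    gamma = config$gamma,
    n_runs = config$n_runs,
    quality_variant = config$variant,
    window = list(length = config$window$length, step = config$window$step,
                  taper = config$window$taper_desc),
    state_fraction = config$state_fraction,
    group_mean_q = mm$group_mean_q,
    n_subjects = nrow(mm$measures),
    simulation = if (!is.null(config$simulation)) unclass(config$simulation),
    runtimes_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(measures = mm, report = report, sweep = sweep,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_result")
}
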