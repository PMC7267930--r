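# Synthetic cohort generator: determinism, validation, planted structure.

test_that("identical configs generate bit-identical cohorts", {
  cfg <- toy_sim_config()
  a <- generate_subject_timeseries(cfg, 2)
  b <- generate_subject_timeseries(cfg, 2)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$amplitude, b$truth$amplitude)

  ca <- generate_cohort(cfg)
  cb <- generate_cohort(cfg)
  expect_identical(ca$phenotype, cb$phenotype)
  expect_identical(ca$series[[3]]$data, cb$series[[3]]$data)
  # different seed changes the data
  cfg2 <- toy_sim_config()
  cfg2$seed <- 100L
  expect_false(identical(generate_subject_timeseries(cfg2, 2)$series$data,
                         a$series$data))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_subjects = 0), class = "dynmod_invalid_config")
  expect_error(simulation_config(n_timepoints = -5), class = "dynmod_invalid_config")
  expect_error(simulation_config(base_between_cov = 0.7, base_within_cov = 0.6),
               class = "dynmod_invalid_config")
  expect_error(simulation_config(stability_range = c(0.5, 0.1)),
               class = "dynmod_invalid_config")
  expect_error(generate_cohort(simulation_config(n_subjects = 2)),
               class = "dynmod_invalid_config")
  cfg <- toy_sim_config()
  expect_error(generate_subject_timeseries(cfg, 99), class = "dynmod_invalid_config")
})

test_that("single-module config yields an all-ones coclassification matrix", {
  cfg <- simulation_config(n_subjects = 3, n_nodes = 16, n_timepoints = 240,
                           n_modules = 1, base_within_cov = 0.7,
                           base_between_cov = 0, noise_sd = 0.2, seed = 5)
  s <- generate_subject_timeseries(cfg, 1)$series
  stk <- connectivity_stack(s, toy_window())
  tr <- q_trace(stk, gamma = 0.5, n_runs = 10, base_seed = 3)
  co <- stability_matrix(tr$partitions)
  expect_true(all(co$values[upper.tri(co$values)] > 0.99))
})

test_that("phenotype tracks planted amplitude with the configured slope", {
  cfg <- simulation_config(n_subjects = 100, n_nodes = 10, n_timepoints = 50,
                           n_modules = 2, phenotype_slope = -60,
                           phenotype_noise_sd = 0.5, seed = 21)
  coh <- generate_cohort(cfg)
  amp <- vapply(coh$truth, `[[`, numeric(1), "amplitude")
  rho <- cor(amp, coh$phenotype$fsiq, method = "spearman")
  expect_lt(rho, -0.8)

  # null slope: correlation centered on zero across seeds
  rhos <- vapply(1:10, function(s) {
    cfg0 <- simulation_config(n_subjects = 60, n_nodes = 10, n_timepoints = 50,
                              n_modules = 2, phenotype_slope = 0, seed = s)
    c0 <- generate_cohort(cfg0)
    a0 <- vapply(c0$truth, `[[`, numeric(1), "amplitude")
    cor(a0, c0$phenotype$fsiq, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("phenotype stays on the IQ scale and covariates are plausible", {
  coh <- generate_cohort(toy_sim_config())
  ph <- coh$phenotype
  expect_true(all(ph$fsiq >= 55 & ph$fsiq <= 145))
  expect_true(all(ph$sex %in% 0:1))
  expect_true(all(ph$handedness %in% 0:1))
  expect_true(all(ph$mean_fd > 0))
  expect_true(all(ph$age >= 18 & ph$age <= 85))
})

test_that("FD confound option induces the requested phenotype correlation", {
  cfg <- simulation_config(n_subjects = 200, n_nodes = 10, n_timepoints = 50,
                           n_modules = 2, fd_phenotype_cor = 0.4, seed = 31)
  coh <- generate_cohort(cfg)
  r <- cor(coh$phenotype$mean_fd, coh$phenotype$fsiq)
  expect_lt(abs(r - 0.4), 0.1)
  # default: independent
  cfg0 <- simulation_config(n_subjects = 200, n_nodes = 10, n_timepoints = 50,
                            n_modules = 2, seed = 31)
  r0 <- cor(generate_cohort(cfg0)$phenotype$mean_fd,
            generate_cohort(cfg0)$phenotype$fsiq)
  expect_lt(abs(r0), 0.2)
})

test_that("planted modules are recovered from static networks at gamma 1", {
  cfg <- simulation_config(n_subjects = 20, seed = 11)
  truth <- planted_modules(cfg)
  nmi <- vapply(1:20, function(i) {
    s <- generate_subject_timeseries(cfg, i)$series
    p <- best_partition(static_connectivity(s), gamma = 1, n_runs = 20,
                        base_seed = 5)
    partition_mutual_information(p$assignment, truth, normalized = TRUE)
  }, numeric(1))
  expect_gte(mean(nmi >= 0.9), 0.9)
})

test_that("downstream SD(Q) increases with the planted amplitude", {
  levels <- c(0, 0.2, 0.4)
  mean_sd <- vapply(levels, function(a) {
    cfg <- simulation_config(n_subjects = 12, stability_range = c(a, a),
                             seed = 17)
    mean(vapply(1:12, function(i) {
      s <- generate_subject_timeseries(cfg, i)$series
      tr <- q_trace(connectivity_stack(s), gamma = 1, n_runs = 5,
                    base_seed = 23)
      sd_q(tr)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sd) > 0))
  # zero-amplitude traces sit near the sampling-noise floor, far below max
  expect_gt(mean_sd[3], 2 * mean_sd[1])
})

test_that("written cohorts round-trip through the readers", {
  coh <- generate_cohort(toy_sim_config())
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  s1 <- read_timeseries(file.path(dir, "sub0001.tsv"), tr = coh$config$tr)
  expect_equal(s1$data, coh$series[[1]]$data, tolerance = 1e-7,
               ignore_attr = TRUE)
  ph <- read_phenotype(file.path(dir, "phenotype.csv"))
  expect_equal(ph$fsiq, coh$phenotype$fsiq, tolerance = 1e-12)
  lab <- read_node_labeling(file.path(dir, "labeling.tsv"))
  expect_identical(lab$network_7, coh$labeling$network_7)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt$subjects, 4)
})
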