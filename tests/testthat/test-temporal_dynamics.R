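# Modularity traces, SD(Q), state detection, sweeps, state profiles.

test_that("sd_q implements the sample standard deviation", {
  expect_equal(sd_q(c(0.2, 0.3, 0.4)), 0.1, tolerance = 1e-12)
  expect_identical(sd_q(rep(0.3, 5)), 0)
  set.seed(1)
  for (rep in 1:20) {
    q <- runif(sample(2:50, 1))
    # two-pass oracle
    m <- sum(q) / length(q)
    oracle <- sqrt(sum((q - m)^2) / (length(q) - 1))
    expect_equal(sd_q(q), oracle, tolerance = 1e-12)
    expect_equal(sd_q(2 * q), 2 * sd_q(q), tolerance = 1e-12)
  }
  expect_error(sd_q(0.5), class = "dynmod_degenerate_input")
})

test_that("state detection arithmetic is exact and strict at thresholds", {
  tr <- c(0.10, 0.30, 0.30, 0.50)
  st <- detect_states(tr, "individual", fraction = 0.5)
  expect_equal(st$high_threshold, 0.45, tolerance = 1e-12)
  expect_equal(st$low_threshold, 0.15, tolerance = 1e-12)
  expect_identical(st$n_high, 1L)
  expect_identical(st$n_low, 1L)
  expect_identical(st$high_window_indices, 4L)
  expect_identical(st$low_window_indices, 1L)

  grp <- detect_states(tr, "group", reference_mean = 0.30, fraction = 0.5)
  expect_identical(grp[c("n_high", "n_low", "high_window_indices",
                         "low_window_indices")],
                   st[c("n_high", "n_low", "high_window_indices",
                        "low_window_indices")])

  # a value exactly at a threshold is not a state (dyadic values: exact)
  at <- detect_states(c(0.25, 0.50, 0.75), "individual", fraction = 0.5)
  expect_identical(at$n_high, 0L)
  expect_identical(at$n_low, 0L)

  expect_error(detect_states(c(-0.2, 0.1), "individual"),
               class = "dynmod_invalid_config")
  expect_error(detect_states(tr, "group"), class = "dynmod_invalid_config")
})

test_that("individual-convention counts are scale invariant", {
  set.seed(8)
  for (rep in 1:20) {
    q <- runif(30, 0.1, 0.5)
    s1 <- detect_states(q, "individual", fraction = 0.3)
    s2 <- detect_states(q * runif(1, 0.5, 5), "individual", fraction = 0.3)
    expect_identical(s1$n_high, s2$n_high)
    expect_identical(s1$n_low, s2$n_low)
  }
})

test_that("group mean follows the subjects-then-windows averaging order", {
  traces <- list(c(0.1, 0.2, 0.6), c(0.3, 0.4, 0.2))
  expect_equal(group_mean_q(traces), mean(c(0.2, 0.3, 0.4)), tolerance = 1e-12)
  expect_error(group_mean_q(list(1:3, 1:2)), class = "dynmod_contract_error")
})

test_that("threshold sweep counts shrink as the band widens", {
  set.seed(12)
  traces <- lapply(1:6, function(i) runif(40, 0.05, 0.6))
  names(traces) <- paste0("s", 1:6)
  sw <- threshold_sweep(traces, "individual",
                        fractions = seq(0.05, 0.95, by = 0.05))
  expect_identical(nrow(sw), 6L * 19L)
  for (id in unique(sw$subject_id)) {
    sub <- sw[sw$subject_id == id, ]
    sub <- sub[order(sub$fraction), ]
    expect_true(all(diff(sub$n_high) <= 0))
    expect_true(all(diff(sub$n_low) <= 0))
  }
  empty <- threshold_sweep(traces, "individual", fractions = numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_error(threshold_sweep(traces, fractions = c(0.5, 1.5)),
               class = "dynmod_invalid_config")
})

test_that("repeated matrices give flat traces, modulated coupling variable ones", {
  # near-identical planted matrix across windows: SD(Q) at the noise floor
  set.seed(41)
  base <- planted_graph(30, k = 3, within = 0.6, between = 0.1, noise = 0)$w
  mats <- lapply(1:12, function(k) {
    e <- matrix(rnorm(900, sd = 0.005), 30)
    m <- base + (e + t(e)) / 2
    diag(m) <- 0
    m
  })
  tr_flat <- q_trace(toy_stack(mats), gamma = 1, n_runs = 10, base_seed = 2)
  expect_lt(sd_q(tr_flat), 0.02)
  expect_equal(tr_flat$mean_q, mean(tr_flat$q_values), tolerance = 1e-12)
  # stored per-window q values recompute from the stored partitions
  k <- 3
  expect_equal(tr_flat$q_values[k],
               modularity_q(mats[[k]], tr_flat$partitions[[k]]$assignment,
                            gamma = 1),
               tolerance = 1e-10)

  # a planted coupling modulation produces a clearly more variable trace
  flat_cfg <- simulation_config(n_subjects = 1, n_nodes = 40, n_timepoints = 500,
                                n_modules = 4, stability_range = c(0, 0),
                                noise_sd = 0.3, seed = 41)
  mod_cfg <- simulation_config(n_subjects = 1, n_nodes = 40, n_timepoints = 500,
                               n_modules = 4, stability_range = c(0.4, 0.4),
                               noise_sd = 0.3, seed = 41)
  spec <- window_spec(length = 156, step = 20)
  sd_flat <- sd_q(q_trace(connectivity_stack(
    generate_subject_timeseries(flat_cfg, 1)$series, spec),
    gamma = 1, n_runs = 10, base_seed = 2))
  sd_mod <- sd_q(q_trace(connectivity_stack(
    generate_subject_timeseries(mod_cfg, 1)$series, spec),
    gamma = 1, n_runs = 10, base_seed = 2))
  expect_gt(sd_mod, 1.5 * sd_flat)
})

test_that("state profiles recover constructed high/low differences", {
  n <- 14
  lab <- toy_labeling(n)
  base <- matrix(0.5, n, n)
  diag(base) <- 0
  hi <- base; hi[upper.tri(hi)] <- -0.2; hi[lower.tri(hi)] <- -0.2; diag(hi) <- 0
  lo <- base; lo[upper.tri(lo)] <- 0.2; lo[lower.tri(lo)] <- 0.2; diag(lo) <- 0
  mats <- list(hi, lo, hi, lo)
  stk <- toy_stack(mats)
  rep1 <- list(high_window_indices = c(1L, 3L), low_window_indices = c(2L, 4L))
  prof <- state_profiles(list(stk), list(rep1), lab)
  off <- upper.tri(diag(n))
  expect_equal(unique(round(prof$difference[off], 12)), -0.4)
  expect_identical(dim(prof$network_difference), c(7L, 7L))
  expect_equal(unique(as.vector(round(prof$network_difference, 12))), -0.4)

  # identical high and low sets give a zero difference
  rep0 <- list(high_window_indices = c(1L, 2L), low_window_indices = c(1L, 2L))
  prof0 <- state_profiles(list(stk), list(rep0), lab)
  expect_equal(max(abs(prof0$difference)), 0)

  repn <- list(high_window_indices = integer(0), low_window_indices = 1L)
  expect_error(state_profiles(list(stk), list(repn), lab),
               class = "dynmod_insufficient_data")
})
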