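# Partial Spearman machinery, Bonferroni, Mann-Whitney, association suite.

test_that("residualization handles empty, exact, and orthogonal designs", {
  set.seed(14)
  y <- rnorm(30, mean = 5, sd = 2)
  r0 <- residualize(y)
  expect_equal(mean(r0), 0, tolerance = 1e-12)
  expect_equal(sd(r0), 1, tolerance = 1e-12)
  expect_equal(cor(r0, y), 1, tolerance = 1e-12)

  x <- cbind(a = rnorm(30), b = rnorm(30))
  y_lin <- 2 + 3 * x[, 1] - x[, 2]
  expect_lt(sqrt(sum(residualize(y_lin, x)^2)), 1e-8)

  # response orthogonal to the design keeps full correlation with itself
  xo <- cbind(rep(c(-1, 1), 15))
  yo <- rnorm(30)
  yo <- yo - xo %*% qr.solve(crossprod(xo), crossprod(xo, yo)) # orthogonalize
  expect_equal(abs(cor(residualize(drop(yo), xo), drop(yo))), 1,
               tolerance = 1e-10)

  xc <- cbind(a = 1:30, b = 2 * (1:30))
  err <- expect_error(residualize(y, xc), class = "dynmod_rank_deficient")
  expect_match(conditionMessage(err), "b")
})

test_that("partial spearman reduces to plain spearman without covariates", {
  pc <- partial_spearman(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(pc$rho, -1, tolerance = 1e-12)
  set.seed(15)
  for (rep in 1:100) {
    n <- sample(8:60, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    pc <- partial_spearman(x, y)
    expect_equal(pc$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(pc$r_squared, pc$rho^2, tolerance = 1e-12)
    expect_true(pc$p_value > 0 && pc$p_value <= 1)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(16)
  x <- rexp(40)
  y <- rnorm(40) + x
  covs <- cbind(rnorm(40))
  base <- partial_spearman(x, y)$rho
  expect_equal(partial_spearman(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(partial_spearman(x, y^3)$rho, base, tolerance = 1e-12)
  # with covariates, transform invariance applies to the rank-first variant
  b2 <- partial_spearman(x, y, covs, rank_first = TRUE)$rho
  expect_equal(partial_spearman(exp(x), y^3, covs, rank_first = TRUE)$rho, b2,
               tolerance = 1e-12)
})

test_that("degenerate partial spearman inputs are rejected", {
  expect_error(partial_spearman(1:3, c(2, 2, 2), cbind(rnorm(3))),
               class = "dynmod_insufficient_n")
  expect_error(partial_spearman(rep(1, 10), rnorm(10)),
               class = "dynmod_undefined_correlation")
  expect_error(partial_spearman(1:5, 1:4), class = "dynmod_contract_error")
})

test_that("bonferroni threshold matches the 28-comparison value", {
  b <- bonferroni_threshold(0.05, 28)
  expect_equal(b$threshold, 0.05 / 28, tolerance = 1e-15)
  expect_identical(b$rounded, 0.0018)
  expect_identical(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_identical(bonferroni_threshold(0.01, 10)$threshold, 0.001)
  expect_error(bonferroni_threshold(0.05, 0), class = "dynmod_invalid_config")
})

test_that("mann-whitney matches exact enumeration and the reference test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$u, 0)
  expect_identical(mw$method, "exact")
  expect_equal(mw$p_value, 0.1, tolerance = 1e-12)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$z, 0)

  set.seed(17)
  for (rep in 1:20) {
    a <- rnorm(sample(5:15, 1))
    b <- rnorm(sample(5:15, 1)) + rnorm(1)
    mw <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = (mw$method == "exact"),
                                        correct = FALSE))
    expect_equal(mw$u, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "dynmod_contract_error")
})

test_that("mann-whitney detects a one-SD shift in moderate samples", {
  set.seed(18)
  hits <- vapply(1:20, function(s) {
    a <- rnorm(50)
    b <- rnorm(50) + 1
    mann_whitney(a, b)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("association suite mirrors the planted relations", {
  set.seed(19)
  n <- 80
  ph <- data.frame(subject_id = sprintf("s%03d", 1:n),
                   fsiq = rnorm(n, 100, 15), age = runif(n, 18, 80),
                   sex = rbinom(n, 1, 0.5), handedness = rbinom(n, 1, 0.9),
                   mean_fd = runif(n, 0.05, 0.3))
  sdq <- 0.05 - 0.0015 * (ph$fsiq - 100) + rnorm(n, 0, 0.005)
  measures <- data.frame(subject_id = ph$subject_id, sd_q = sdq,
                         mean_q = rnorm(n, 0.25, 0.03),
                         n_high_ind = rbinom(n, 2, 0.2),
                         n_low_ind = rep(0L, n), # degenerate: constant
                         n_high_grp = rbinom(n, 2, 0.2),
                         n_low_grp = rbinom(n, 1, 0.1))
  ns <- matrix(runif(n * 28), n, 28,
               dimnames = list(ph$subject_id,
                               paste0("p", 1:28)))
  rep <- run_association_suite(measures, ph, network_scores = ns)
  corr <- rep$correlations
  expect_identical(nrow(corr), 6L)
  sdq_row <- corr[corr$measure == "sd_q", ]
  expect_lt(sdq_row$rho, 0)
  expect_lt(sdq_row$p_value, 0.001)
  expect_true(is.na(corr$rho[corr$measure == "n_low_ind"]))
  expect_identical(nrow(rep$network), 28L)
  expect_identical(attr(rep$network, "bonferroni")$rounded, 0.0018)
  expect_true(!is.null(rep$contrasts))

  expect_error(run_association_suite(measures[1:3, ], ph),
               class = "dynmod_insufficient_n")
})
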