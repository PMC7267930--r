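# Phenotype association analyses: partial Spearman correlations with
# nuisance covariates, Bonferroni correction, and Mann-Whitney contrasts
# between subjects with and without extreme-modularity states.

#' OLS residuals of a variable on covariates
#'
#' Residualizes `y` on the covariate columns plus an intercept and
#' standardizes the residuals to unit variance (when non-degenerate). With
#' no covariates this simply centers and standardizes `y`.
#'
#' @param y numeric response vector.
#' @param covariates numeric matrix/data.frame with one row per observation,
#'   or `NULL` for none.
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    r <- y - mean(y)
  } else {
    x <- as.matrix(covariates)
    storage.mode(x) <- "double"
    if (nrow(x) != n) {
      stop_dynmod("covariates must have one row per observation",
                  class = "dynmod_contract_error")
    }
    if (n <= ncol(x) + 1L) {
      stop_dynmod("need more observations than covariates + 1",
                  class = "dynmod_contract_error")
    }
    design <- cbind(`(intercept)` = 1, x)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
      stop_dynmod(paste("collinear covariate columns:", paste(dropped, collapse = ", ")),
                  class = "dynmod_rank_deficient")
    }
    r <- qr.resid(qrd, y)
  }
  s <- sd(r)
  if (is.finite(s) && s > 1e-12) r <- r / s
  r
}

# average ranks with tie handling
avg_rank <- function(x) rank(x, ties.method = "average")

#' Partial Spearman correlation
#'
#' Residualizes both variables on the covariates (plus intercept), ranks the
#' residuals with average ranks for ties, and takes the Pearson correlation
#' of the ranks. The two-sided p-value uses the t approximation with
#' `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix/data.frame of nuisance covariates, or
#'   `NULL`.
#' @param rank_first rank the raw variables before residualizing instead of
#'   after (default FALSE: residualize-then-rank).
#' @return list of class `partial_corr`: `rho`, `p_value`, `n`,
#'   `n_covariates`, `r_squared`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, rank_first = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_dynmod("x and y must have equal length", class = "dynmod_contract_error")
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < k + 4L) {
    stop_dynmod(sprintf("need at least %d observations for %d covariates", k + 4L, k),
                class = "dynmod_insufficient_n")
  }
  if (rank_first) {
    x <- avg_rank(x)
    y <- avg_rank(y)
  }
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    stop_dynmod("constant residuals: correlation undefined",
                class = "dynmod_undefined_correlation")
  }
  rho <- cor(avg_rank(rx), avg_rank(ry))
  df <- n - 2L - k
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt(df / (1 - rho^2))
    2 * pt(-abs(tval), df)
  }
  structure(
    list(rho = rho, p_value = p, n = n, n_covariates = k, r_squared = rho^2),
    class = "partial_corr"
  )
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial Spearman: rho = %.3f, p = %.4g, R^2 = %.3f (n = %d, %d covariates)\n",
              x$rho, x$p_value, x$r_squared, x$n, x$n_covariates))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons.
#' @return list with `threshold` (alpha / m, full precision) and `rounded`
#'   (4 decimals).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is_count(m, 1)) stop_dynmod("m must be a positive integer", class = "dynmod_invalid_config")
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) {
    stop_dynmod("alpha must lie in (0, 1]", class = "dynmod_invalid_config")
  }
  th <- alpha / m
  list(threshold = th, rounded = round(th, 4))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums for `group_a` relative to `group_b`. The z
#' statistic uses the normal approximation with tie correction (no
#' continuity correction). When `n_a * n_b <= 400` and there are no ties the
#' p-value comes from the exact U distribution instead.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return list of class `mann_whitney`: `u`, `z`, `p_value`, `method`
#'   (`"exact"` or `"normal"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) {
    stop_dynmod("both groups must be non-empty", class = "dynmod_contract_error")
  }
  pooled <- c(a, b)
  r <- avg_rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (!has_ties && na * nb <= 400) {
    p_lo <- pwilcox(u, na, nb)
    p_hi <- 1 - pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal"
  }
  structure(list(u = u, z = z, p_value = p, method = method, n_a = na, n_b = nb),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, z = %.3f, p = %.4g (%s, n = %d/%d)\n",
              x$u, x$z, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Run the full phenotype association battery
#'
#' Mirrors the study's analysis set on a measures table: partial Spearman
#' correlations (controlling for age, sex, handedness, mean FD) between the
#' phenotype and (i) SD(Q), (ii) time-averaged Q, (iii) state counts under
#' both conventions, and (iv) the 28 network-specific stability scores with
#' Bonferroni correction; plus Mann-Whitney contrasts of phenotype and mean
#' FD between subjects with and without extreme states.
#'
#' @param measures data.frame keyed by `subject_id` with numeric columns
#'   `sd_q`, `mean_q`, `n_high_ind`, `n_low_ind`, `n_high_grp`, `n_low_grp`
#'   (missing columns are skipped).
#' @param phenotype phenotype table covering all subjects.
#' @param network_scores optional subject x 28 matrix of network stability
#'   scores (rownames = subject ids).
#' @param covariates covariate column names in `phenotype`.
#' @param alpha family-wise error rate for the network battery.
#' @return list of class `association_report` with data.frames
#'   `correlations`, `network` (with `significant_bonferroni` flags and the
#'   corrected threshold as attribute), and `contrasts`.
#' @export
run_association_suite <- function(measures, phenotype, network_scores = NULL,
                                  covariates = c("age", "sex", "handedness", "mean_fd"),
                                  alpha = 0.05) {
  phenotype <- validate_phenotype(phenotype)
  if (!"subject_id" %in% names(measures)) {
    stop_dynmod("measures must have a subject_id column", class = "dynmod_contract_error")
  }
  idx <- match(measures$subject_id, phenotype$subject_id)
  if (anyNA(idx)) {
    stop_dynmod("phenotype does not cover all measured subjects",
                class = "dynmod_contract_error")
  }
  ph <- phenotype[idx, , drop = FALSE]
  n <- nrow(ph)
  k <- length(covariates)
  if (n < k + 4L) {
    stop_dynmod(sprintf("need at least %d subjects for %d covariates, got %d",
                        k + 4L, k, n),
                class = "dynmod_insufficient_n")
  }
  covm <- as.matrix(ph[, covariates, drop = FALSE])
  constant <- apply(covm, 2, function(v) sd(v) < 1e-12)
  if (any(constant)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(covariates[constant], collapse = ", ")))
    covm <- covm[, !constant, drop = FALSE]
    covariates <- covariates[!constant]
    k <- length(covariates)
  }
  fsiq <- ph$fsiq

  measure_cols <- intersect(
    c("sd_q", "mean_q", "n_high_ind", "n_low_ind", "n_high_grp", "n_low_grp"),
    names(measures)
  )
  # a measure with (near-)constant residuals (e.g. a state count of zero for
  # everyone) has no defined correlation: report NA instead of failing
  safe_partial <- function(x) {
    tryCatch(partial_spearman(x, fsiq, covm),
             dynmod_undefined_correlation = function(e) {
               list(rho = NA_real_, p_value = NA_real_, r_squared = NA_real_,
                    n = n)
             })
  }
  correlations <- do.call(rbind, lapply(measure_cols, function(col) {
    pc <- safe_partial(measures[[col]])
    data.frame(measure = col, rho = pc$rho, p_value = pc$p_value,
               r_squared = pc$r_squared, n = pc$n, stringsAsFactors = FALSE)
  }))

  network <- NULL
  if (!is.null(network_scores)) {
    ns <- as.matrix(network_scores)
    if (!is.null(rownames(ns))) {
      ns <- ns[match(measures$subject_id, rownames(ns)), , drop = FALSE]
    }
    bon <- bonferroni_threshold(alpha, ncol(ns))
    network <- do.call(rbind, lapply(seq_len(ncol(ns)), function(j) {
      pc <- safe_partial(ns[, j])
      data.frame(pair = colnames(ns)[j], rho = pc$rho, p_value = pc$p_value,
                 r_squared = pc$r_squared,
                 significant_bonferroni = !is.na(pc$p_value) &&
                   pc$p_value < bon$threshold,
                 stringsAsFactors = FALSE)
    }))
    attr(network, "bonferroni") <- bon
  }

  contrasts <- NULL
  contrast_one <- function(count_col, value, value_name) {
    has <- measures[[count_col]] > 0
    if (!any(has) || all(has)) return(NULL)
    mw <- mann_whitney(value[has], value[!has])
    data.frame(states = count_col, outcome = value_name, u = mw$u, z = mw$z,
               p_value = mw$p_value, method = mw$method,
               n_with = sum(has), n_without = sum(!has),
               stringsAsFactors = FALSE)
  }
  for (col in intersect(c("n_high_ind", "n_low_ind"), measure_cols)) {
    contrasts <- rbind(contrasts,
                       contrast_one(col, fsiq, "fsiq"),
                       contrast_one(col, ph$mean_fd, "mean_fd"))
  }

  structure(list(correlations = correlations, network = network,
                 contrasts = contrasts, n = n, covariates = covariates),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("association report (n = %d, covariates: %s)\n", x$n,
              paste(x$covariates, collapse = ", ")))
  print(x$correlations, row.names = FALSE)
  if (!is.null(x$network)) {
    bon <- attr(x$network, "bonferroni")
    cat(sprintf("network battery: %d/%d pass Bonferroni (threshold %.4f)\n",
                sum(x$network$significant_bonferroni), nrow(x$network),
                bon$rounded))
  }
  if (!is.null(x$contrasts)) print(x$contrasts, row.names = FALSE)
  invisible(x)
}
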