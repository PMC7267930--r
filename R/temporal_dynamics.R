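# Per-subject modularity trace, temporal-stability statistic, extreme-state
# detection, threshold sensitivity sweep, and state-conditioned group
# connectivity profiles.

#' Window-wise modularity trace
#'
#' Runs multi-restart Louvain on every window matrix at a fixed resolution
#' and records modularity, module count and the partition per window.
#'
#' @param stack a [connectivity_stack()].
#' @param gamma resolution parameter.
#' @param n_runs Louvain restarts per window.
#' @param base_seed master seed; each window uses a derived restart block.
#' @param variant quality-function variant, see [modularity_q()].
#' @return object of class `modularity_trace`: `q_values`,
#'   `n_modules_values`, `partitions` (list), `mean_q`, `gamma`,
#'   `subject_id`.
#' @export
q_trace <- function(stack, gamma = 1, n_runs = 100L, base_seed = 1L,
                    variant = "signed") {
  stopifnot(inherits(stack, "connectivity_stack"))
  n_win <- dim(stack$matrices)[3]
  if (n_win < 1L) stop_dynmod("need at least one window", class = "dynmod_contract_error")
  variant <- match.arg(variant, QUALITY_VARIANTS)
  if (!is_number(gamma) || gamma <= 0) {
    stop_dynmod("gamma must be positive", class = "dynmod_contract_error")
  }
  n <- dim(stack$matrices)[1]
  node_ids <- dimnames(stack$matrices)[[1]]
  if (is.null(node_ids)) node_ids <- node_id_labels(n)
  wseeds <- vapply(seq_len(n_win), function(k) derive_seed(base_seed, k), integer(1))
  res <- louvain_stack_cpp(stack$matrices, n, n_win, gamma, wseeds,
                           as.integer(n_runs), variant, 1e-10, 100L)
  parts <- lapply(seq_len(n_win), function(k) {
    new_partition(res$assignment[, k], node_ids, gamma, res$q[k],
                  res$run_seed[k], variant)
  })
  qs <- as.numeric(res$q)
  nmod <- as.numeric(res$n_modules)
  structure(
    list(q_values = qs, n_modules_values = nmod, partitions = parts,
         mean_q = mean(qs), gamma = gamma, subject_id = stack$subject_id),
    class = "modularity_trace"
  )
}

#' @export
print.modularity_trace <- function(x, ...) {
  cat(sprintf("modularity_trace '%s': %d windows, gamma = %g, mean Q = %.4f, SD(Q) = %.4f\n",
              x$subject_id, length(x$q_values), x$gamma, x$mean_q,
              if (length(x$q_values) > 1) sd(x$q_values) else 0))
  invisible(x)
}

#' Temporal variability of modularity
#'
#' Sample standard deviation (n - 1 denominator) of the window-wise
#' modularity values: the temporal-stability statistic (lower = more
#' stable).
#'
#' @param trace a `modularity_trace` or a numeric vector of Q values.
#' @return non-negative scalar.
#' @export
sd_q <- function(trace) {
  q <- if (inherits(trace, "modularity_trace")) trace$q_values else as.numeric(trace)
  if (length(q) < 2L) {
    stop_dynmod("SD over time needs at least 2 windows", class = "dynmod_degenerate_input")
  }
  sd(q)
}

#' Group mean modularity
#'
#' Averages the window-wise modularity first across subjects (per window)
#' and then across windows, in that order.
#'
#' @param traces list of `modularity_trace` with equal window counts.
#' @return scalar group mean.
#' @export
group_mean_q <- function(traces) {
  qlist <- lapply(traces, function(tr) {
    if (inherits(tr, "modularity_trace")) tr$q_values else as.numeric(tr)
  })
  if (length(unique(lengths(qlist))) != 1L) {
    stop_dynmod("all traces must have the same number of windows",
                class = "dynmod_contract_error")
  }
  mean(rowMeans(do.call(cbind, qlist)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect extreme-modularity states
#'
#' A window is a high-modularity state when its Q strictly exceeds
#' `M * (1 + fraction)` and a low-modularity state when it falls strictly
#' below `M * (1 - fraction)`, where M is the subject's own mean Q
#' (`convention = "individual"`) or a supplied group mean
#' (`convention = "group"`).
#'
#' @param trace a `modularity_trace` or numeric Q vector.
#' @param convention `"individual"` or `"group"`.
#' @param reference_mean group mean Q (required for the group convention).
#' @param fraction threshold half-width as a fraction of the mean
#'   (default 0.5).
#' @return list of class `state_report`: `convention`, `fraction`,
#'   `high_threshold`, `low_threshold`, `n_high`, `n_low`,
#'   `high_window_indices`, `low_window_indices`.
#' @export
detect_states <- function(trace, convention = c("individual", "group"),
                          reference_mean = NULL, fraction = 0.5) {
  convention <- match.arg(convention)
  q <- if (inherits(trace, "modularity_trace")) trace$q_values else as.numeric(trace)
  if (length(q) == 0L) stop_dynmod("empty trace", class = "dynmod_degenerate_input")
  if (!is_number(fraction) || fraction <= 0) {
    stop_dynmod("fraction must be positive", class = "dynmod_invalid_config")
  }
  m <- if (convention == "individual") {
    mean(q)
  } else {
    if (!is_number(reference_mean)) {
      stop_dynmod("group convention needs a reference_mean", class = "dynmod_invalid_config")
    }
    reference_mean
  }
  if (m <= 0) {
    stop_dynmod("thresholds undefined for a non-positive mean modularity",
                class = "dynmod_invalid_config")
  }
  hi <- m * (1 + fraction)
  lo <- m * (1 - fraction)
  high_idx <- which(q > hi)
  low_idx <- which(q < lo)
  structure(
    list(convention = convention, fraction = fraction,
         high_threshold = hi, low_threshold = lo,
         n_high = length(high_idx), n_low = length(low_idx),
         high_window_indices = high_idx, low_window_indices = low_idx),
    class = "state_report"
  )
}

#' Threshold sensitivity sweep of state counts
#'
#' Re-runs [detect_states()] across a ladder of threshold fractions for every
#' subject and returns a long table for downstream per-fraction
#' correlations.
#'
#' @param traces named list of `modularity_trace` (or Q vectors).
#' @param convention `"individual"` or `"group"`.
#' @param fractions threshold fractions in (0, 1).
#' @param reference_mean group mean Q (group convention only).
#' @return data.frame with columns `subject_id`, `fraction`, `n_high`,
#'   `n_low`.
#' @export
threshold_sweep <- function(traces, convention = c("individual", "group"),
                            fractions = seq(0.05, 0.95, by = 0.05),
                            reference_mean = NULL) {
  convention <- match.arg(convention)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop_dynmod("fractions must lie in (0, 1)", class = "dynmod_invalid_config")
  }
  ids <- names(traces)
  if (is.null(ids)) {
    ids <- vapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      if (inherits(tr, "modularity_trace")) tr$subject_id else sprintf("sub%04d", i)
    }, character(1))
  }
  rows <- lapply(seq_along(traces), function(i) {
    per <- lapply(fractions, function(f) {
      rep <- detect_states(traces[[i]], convention = convention,
                           reference_mean = reference_mean, fraction = f)
      data.frame(subject_id = ids[i], fraction = f,
                 n_high = rep$n_high, n_low = rep$n_low,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), fraction = numeric(),
                      n_high = integer(), n_low = integer())
  }
  rownames(out) <- NULL
  out
}

#' State-conditioned group connectivity profiles
#'
#' Pools high-state and low-state windows across the cohort, averages the
#' corresponding connectivity matrices element-wise, forms the high-minus-low
#' difference matrix, and aggregates that difference within and between the
#' seven canonical networks (hemispheres merged, diagonal cells excluded).
#'
#' @param stacks list of [connectivity_stack()], one per subject.
#' @param reports list of `state_report`, aligned with `stacks`.
#' @param labeling node labeling covering the stack's nodes.
#' @return list: `high_mean`, `low_mean`, `difference` (node x node), and
#'   `network_difference` (7 x 7 symmetric matrix of block means).
#' @export
state_profiles <- function(stacks, reports, labeling) {
  stopifnot(length(stacks) == length(reports))
  labeling <- validate_node_labeling(labeling)
  sum_high <- sum_low <- NULL
  n_high <- n_low <- 0L
  for (i in seq_along(stacks)) {
    m <- stacks[[i]]$matrices
    if (is.null(sum_high)) {
      sum_high <- sum_low <- matrix(0, dim(m)[1], dim(m)[2],
                                    dimnames = dimnames(m)[1:2])
    }
    for (k in reports[[i]]$high_window_indices) {
      sum_high <- sum_high + m[, , k]
      n_high <- n_high + 1L
    }
    for (k in reports[[i]]$low_window_indices) {
      sum_low <- sum_low + m[, , k]
      n_low <- n_low + 1L
    }
  }
  if (n_high == 0L || n_low == 0L) {
    stop_dynmod(sprintf("need at least one high and one low state window across the cohort (found %d high, %d low)",
                        n_high, n_low),
                class = "dynmod_insufficient_data")
  }
  high_mean <- sum_high / n_high
  low_mean <- sum_low / n_low
  diff <- high_mean - low_mean
  list(high_mean = high_mean, low_mean = low_mean, difference = diff,
       network_difference = aggregate_network_blocks(diff, labeling))
}

# 7 x 7 block means of a node x node matrix (hemispheres merged, self-cells
# excluded); shared by state profiles and network stability scores.
aggregate_network_blocks <- function(m, labeling) {
  nets <- yeo7_networks()
  lab <- labeling$network_7[match(rownames(m) %||% labeling$node_id, labeling$node_id)]
  if (anyNA(lab)) {
    stop_dynmod("labeling does not cover all matrix nodes", class = "dynmod_contract_error")
  }
  out <- matrix(NA_real_, 7, 7, dimnames = list(nets, nets))
  for (i in seq_len(7)) {
    for (j in i:7) {
      ri <- which(lab == nets[i])
      rj <- which(lab == nets[j])
      if (length(ri) == 0 || length(rj) == 0) {
        stop_dynmod(sprintf("network %s has no nodes", nets[if (length(ri) == 0) i else j]),
                    class = "dynmod_contract_error")
      }
      block <- m[ri, rj, drop = FALSE]
      if (i == j) {
        keep <- outer(ri, rj, "!=") # exclude self-pairs on the block diagonal
        v <- mean(block[keep])
      } else {
        v <- mean(block)
      }
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}
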