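# Resolution-parameterized modularity for signed weighted graphs and
# multi-restart Louvain optimization.

QUALITY_VARIANTS <- c("signed", "positive", "plain")

check_connectivity_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop_dynmod("connectivity matrix must be a square numeric matrix",
                class = "dynmod_contract_error")
  }
  if (any(!is.finite(m))) {
    stop_dynmod("connectivity matrix must be finite", class = "dynmod_contract_error")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop_dynmod("connectivity matrix must be symmetric", class = "dynmod_contract_error")
  }
  m
}

# positive/negative decomposition honoring the quality-function variant
signed_parts <- function(m, variant) {
  variant <- match.arg(variant, QUALITY_VARIANTS)
  if (variant == "plain") {
    list(wp = m, wn = matrix(0, nrow(m), ncol(m)))
  } else if (variant == "positive") {
    list(wp = pmax(m, 0), wn = matrix(0, nrow(m), ncol(m)))
  } else {
    list(wp = pmax(m, 0), wn = pmax(-m, 0))
  }
}

#' Modularity of a partition on a signed weighted graph
#'
#' For a non-negative matrix this is Newman-Girvan weighted modularity with
#' resolution gamma,
#' `Q = (1/2m) * sum_ij (w_ij - gamma * k_i * k_j / (2m)) * delta(c_i, c_j)`.
#' For matrices with negative entries the default `"signed"` variant uses the
#' asymmetric signed quality `Q* = Q+ - (v- / (v+ + v-)) * Q-`, where `Q+`
#' and `Q-` are the Newman terms of the positive and negative parts and
#' `v+`, `v-` their total weights. `"positive"` discards negative edges and
#' `"plain"` applies the Newman formula to the raw matrix.
#'
#' @param matrix square symmetric numeric matrix (zero diagonal for node
#'   graphs; aggregated graphs may carry self-loops).
#' @param assignment integer module ids, one per node.
#' @param gamma resolution parameter (> 0).
#' @param variant `"signed"` (default), `"positive"` or `"plain"`.
#' @return modularity value (finite scalar).
#' @export
modularity_q <- function(matrix, assignment, gamma = 1, variant = "signed") {
  m <- check_connectivity_matrix(matrix)
  variant <- match.arg(variant, QUALITY_VARIANTS)
  assignment <- as.integer(assignment)
  if (length(assignment) != nrow(m) || anyNA(assignment)) {
    stop_dynmod("assignment must cover every node", class = "dynmod_contract_error")
  }
  if (!is_number(gamma) || gamma <= 0) {
    stop_dynmod("gamma must be positive", class = "dynmod_contract_error")
  }
  parts <- signed_parts(m, variant)
  m2p <- sum(parts$wp)
  m2n <- sum(parts$wn)
  if (variant == "plain" && m2p <= 0) {
    stop_dynmod("plain quality undefined: total weight must be positive",
                class = "dynmod_undefined_quality")
  }
  if (m2p + m2n <= 0) {
    stop_dynmod("quality undefined for an all-zero matrix",
                class = "dynmod_undefined_quality")
  }
  qhat <- function(w, m2) {
    blocks <- rowsum(t(rowsum(w, assignment)), assignment) # module x module sums
    k_mod <- rowsum(rowSums(w), assignment)
    (sum(diag(blocks)) - gamma * sum(k_mod^2) / m2) / m2
  }
  if (m2p <= 0) { # negative-only graph: only the (down-weighted) Q- term survives
    return(-qhat(parts$wn, m2n))
  }
  q <- qhat(parts$wp, m2p)
  if (m2n > 0) q <- q - (m2n / (m2p + m2n)) * qhat(parts$wn, m2n)
  q
}

new_partition <- function(assignment, node_ids, gamma, q, run_seed, variant) {
  assignment <- as.integer(assignment)
  names(assignment) <- node_ids
  structure(
    list(assignment = assignment, gamma = gamma, q = q,
         n_modules = length(unique(assignment)), run_seed = run_seed,
         variant = variant),
    class = "dynmod_partition"
  )
}

#' @export
print.dynmod_partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes, %d modules, gamma = %g, Q = %.6f (%s quality, seed %d)\n",
              length(x$assignment), x$n_modules, x$gamma, x$q, x$variant,
              x$run_seed))
  invisible(x)
}

#' Single Louvain run
#'
#' Two-phase Louvain: greedy local node moves to the neighboring module with
#' the largest quality gain (until no gain exceeds `tol`), then aggregation
#' of modules into nodes, repeated until stable. The node sweep order is
#' shuffled by `seed`, making each run fully deterministic.
#'
#' @param matrix symmetric connectivity matrix.
#' @param gamma resolution parameter (> 0).
#' @param seed run seed.
#' @param variant quality-function variant, see [modularity_q()].
#' @param tol minimum quality gain for a move (default 1e-10).
#' @param max_pass maximum aggregation passes (default 100).
#' @return a `dynmod_partition` with module ids canonicalized by first
#'   appearance in node order and `q` recomputed from scratch on the input
#'   matrix.
#' @export
louvain_once <- function(matrix, gamma = 1, seed = 1L, variant = "signed",
                         tol = 1e-10, max_pass = 100L) {
  best_partition(matrix, gamma, n_runs = 1L, base_seed = seed,
                 variant = variant, tol = tol, max_pass = max_pass)
}

#' Best partition over multiple Louvain restarts
#'
#' Runs [louvain_once()] with seeds `base_seed, ..., base_seed + n_runs - 1`
#' and returns the maximum-quality partition; ties break to the lowest seed.
#'
#' @param matrix symmetric connectivity matrix.
#' @param gamma resolution parameter (> 0).
#' @param n_runs number of restarts (default 100).
#' @param base_seed seed of the first restart.
#' @param variant quality-function variant, see [modularity_q()].
#' @param tol minimum quality gain for a move.
#' @param max_pass maximum aggregation passes.
#' @return a `dynmod_partition`; the per-run qualities are attached as
#'   attribute `"run_q"`.
#' @export
best_partition <- function(matrix, gamma = 1, n_runs = 100L, base_seed = 1L,
                           variant = "signed", tol = 1e-10, max_pass = 100L) {
  m <- check_connectivity_matrix(matrix)
  variant <- match.arg(variant, QUALITY_VARIANTS)
  if (!is_number(gamma) || gamma <= 0) {
    stop_dynmod("gamma must be positive", class = "dynmod_contract_error")
  }
  if (!is_count(n_runs, 1)) {
    stop_dynmod("n_runs must be a positive integer", class = "dynmod_contract_error")
  }
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  res <- louvain_best_cpp(m, gamma, seeds, variant, tol, as.integer(max_pass))
  node_ids <- rownames(m)
  if (is.null(node_ids)) node_ids <- node_id_labels(nrow(m))
  q <- modularity_q(m, res$assignment, gamma = gamma, variant = variant)
  p <- new_partition(res$assignment, node_ids, gamma, q, res$run_seed, variant)
  attr(p, "run_q") <- res$run_q
  p
}
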