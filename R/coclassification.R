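# Coclassification (module allegiance): window-wise binary coclassification,
# time-averaged connection stability, and network-level aggregation into the
# 28 within/between scores of the seven canonical networks.

#' Binary coclassification matrix of one partition
#'
#' Entry (i, j) is 1 when nodes i and j share a module in the given
#' partition, else 0; the diagonal is 1.
#'
#' @param partition a `dynmod_partition` or an assignment vector.
#' @return binary node x node matrix.
#' @export
window_coclassification <- function(partition) {
  a <- if (inherits(partition, "dynmod_partition")) partition$assignment else partition
  if (length(a) == 0L || anyNA(a)) {
    stop_dynmod("partition must assign every node", class = "dynmod_contract_error")
  }
  m <- outer(a, a, "==") * 1
  if (!is.null(names(a))) dimnames(m) <- list(names(a), names(a))
  m
}

#' Time-averaged coclassification (stability) matrix
#'
#' Element-wise mean of the binary window coclassification matrices: the
#' proportion of windows in which each node pair shares a module. Values lie
#' in `[0, 1]` with a unit diagonal.
#'
#' @param partitions list of partitions over windows (consistent node sets).
#' @return object of class `coclassification_matrix`: list with `values`
#'   (node x node) and `n_windows`.
#' @export
stability_matrix <- function(partitions) {
  if (length(partitions) == 0L) {
    stop_dynmod("need at least one partition", class = "dynmod_contract_error")
  }
  mats <- lapply(partitions, window_coclassification)
  dims <- vapply(mats, nrow, integer(1))
  ids <- lapply(mats, rownames)
  if (length(unique(dims)) != 1L ||
      (!is.null(ids[[1]]) && !all(vapply(ids, identical, logical(1), ids[[1]])))) {
    stop_dynmod("partitions cover inconsistent node sets", class = "dynmod_contract_error")
  }
  acc <- Reduce(`+`, mats) / length(mats)
  structure(list(values = acc, n_windows = length(mats)),
            class = "coclassification_matrix")
}

#' @export
print.coclassification_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("coclassification_matrix: %d nodes over %d windows, mean off-diagonal = %.3f\n",
              nrow(x$values), x$n_windows, mean(off)))
  invisible(x)
}

#' Network-specific stability profile (28 scores)
#'
#' Averages the coclassification scores of all connections within and
#' between the seven canonical networks (hemispheres merged, diagonal
#' self-pairs excluded): 7 within-network plus 21 between-network scores, in
#' fixed order (within VIS..DMN first, then the between pairs in row-major
#' upper-triangle order).
#'
#' @param matrix a `coclassification_matrix` (or plain node x node matrix in
#'   `[0, 1]`).
#' @param labeling node labeling with the 7-network scheme.
#' @param include_diagonal include self-pairs in within-network means
#'   (default FALSE; self-coclassification is trivially 1).
#' @return named numeric vector of 28 scores (names like `"VIS-VIS"`,
#'   `"VIS-SMN"`, ...).
#' @export
network_stability <- function(matrix, labeling, include_diagonal = FALSE) {
  m <- if (inherits(matrix, "coclassification_matrix")) matrix$values else matrix
  labeling <- validate_node_labeling(labeling)
  # score the networks present in the labeling, in canonical order; a full
  # 7-network labeling yields the 28 within/between scores
  nets <- yeo7_networks()[yeo7_networks() %in% unique(labeling$network_7)]
  if (length(nets) < 1L) {
    stop_dynmod("labeling declares no networks", class = "dynmod_contract_error")
  }
  lab <- labeling$network_7[match(rownames(m) %||% labeling$node_id, labeling$node_id)]
  if (anyNA(lab) || length(lab) != nrow(m)) {
    stop_dynmod("labeling does not cover all matrix nodes", class = "dynmod_contract_error")
  }
  idx <- lapply(nets, function(nw) which(lab == nw))
  names(idx) <- nets
  if (any(lengths(idx) == 0L)) {
    stop_dynmod("every network needs at least one node", class = "dynmod_contract_error")
  }
  pairs <- network_pair_order(nets)
  out <- vapply(seq_len(nrow(pairs)), function(r) {
    ri <- idx[[pairs$a[r]]]
    rj <- idx[[pairs$b[r]]]
    block <- m[ri, rj, drop = FALSE]
    if (pairs$a[r] == pairs$b[r] && !include_diagonal) {
      mean(block[outer(ri, rj, "!=")])
    } else {
      mean(block)
    }
  }, numeric(1))
  names(out) <- paste(pairs$a, pairs$b, sep = "-")
  out
}

# fixed ordering of the unordered network pairs: within pairs first, then
# the between pairs in row-major upper-triangle order (28 for 7 networks)
network_pair_order <- function(nets = yeo7_networks()) {
  k <- length(nets)
  within <- data.frame(a = nets, b = nets, stringsAsFactors = FALSE)
  if (k == 1L) return(within)
  between <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    data.frame(a = nets[i], b = nets[(i + 1):k], stringsAsFactors = FALSE)
  }))
  rbind(within, between)
}

# number of off-diagonal matrix cells behind each of the 28 scores (weights
# under which the block scores average back to the off-diagonal grand mean)
network_pair_sizes <- function(labeling) {
  labeling <- validate_node_labeling(labeling)
  nets <- yeo7_networks()[yeo7_networks() %in% unique(labeling$network_7)]
  counts <- table(factor(labeling$network_7, levels = nets))
  pairs <- network_pair_order(nets)
  vapply(seq_len(nrow(pairs)), function(r) {
    na <- counts[[pairs$a[r]]]
    nb <- counts[[pairs$b[r]]]
    if (pairs$a[r] == pairs$b[r]) na * (na - 1) else 2 * na * nb
  }, numeric(1))
}
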