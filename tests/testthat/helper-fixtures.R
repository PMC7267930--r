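# Small fixtures built in code.

# wrap a list of equal-size square matrices as a connectivity stack
toy_stack <- function(mats, subject_id = "toy") {
  n <- nrow(mats[[1]])
  arr <- array(unlist(mats), dim = c(n, n, length(mats)))
  dimnames(arr) <- list(sprintf("n%03d", 1:n), sprintf("n%03d", 1:n), NULL)
  structure(
    list(matrices = arr,
         windows = data.frame(start = seq_along(mats), end = seq_along(mats)),
         spec = NULL, subject_id = subject_id),
    class = "connectivity_stack"
  )
}

# labeling for a toy node count (wraps the constructor; n must be even)
toy_labeling <- function(n_nodes) make_node_labeling(n_nodes)

# fast simulation config for module-level tests
toy_sim_config <- function(...) {
  simulation_config(n_subjects = 4, n_nodes = 28, n_timepoints = 240,
                    n_modules = 7, seed = 99, ...)
}

# window spec sized for toy series
toy_window <- function() window_spec(length = 80, step = 40)
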