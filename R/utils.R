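# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a stream index so that independent stages
#' (subjects, windows, restarts) get distinct, order-independent seeds.
#' All values stay strictly below 2^31 so they are valid R integers.
#'
#' @param seed master seed (integer).
#' @param stream non-negative stream index.
#' @return an integer seed in `[1, 2147483628]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream), stream >= 0)
  m <- 2147483629 # largest prime < 2^31
  s <- (as.numeric(seed) %% m) * 69621 + (as.numeric(stream) %% m) * 7919 + 1
  as.integer(s %% m + 1)
}

# consistent error helper: all user-facing errors carry a dynmod_error class
stop_dynmod <- function(msg, class = "dynmod_error", ...) {
  stop(structure(
    class = c(class, "dynmod_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# clip to closed interval
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
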