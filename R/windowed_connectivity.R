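# Static and tapered sliding-window weighted connectivity.
#
# Edges are Fisher-z transformed weighted Pearson correlations computed on
# tapered window slices; matrices stay weighted and unthresholded (negative
# edges are kept), with a zero diagonal.

#' Sliding-window specification
#'
#' @param length window length in time points (default 156, about 100 s at
#'   TR = 0.645 s, the full cycle of the slowest band-passed component).
#' @param step shift between consecutive windows in time points (default 10).
#' @param taper per-sample non-negative weights of length `length`, or one of
#'   the shortcuts `"gaussian"` (rectangle convolved with a Gaussian of
#'   `taper_sd` time points, max-normalized — the default) and `"uniform"`.
#' @param taper_sd Gaussian smoothing SD in time points for the default
#'   taper.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 156L, step = 10L, taper = "gaussian",
                        taper_sd = 3) {
  if (!is_count(length, 2) || !is_count(step, 1)) {
    stop_dynmod("window length must be >= 2 and step >= 1", class = "dynmod_invalid_config")
  }
  if (is.character(taper)) {
    taper <- switch(match.arg(taper, c("gaussian", "uniform")),
      gaussian = taper_gaussian(length, taper_sd),
      uniform = rep(1, length)
    )
    taper_desc <- if (all(taper == 1)) "uniform" else sprintf("gaussian:%g", taper_sd)
  } else {
    taper_desc <- "custom"
  }
  taper <- as.numeric(taper)
  if (base::length(taper) != length || any(!is.finite(taper)) || any(taper < 0) ||
      max(taper) <= 0) {
    stop_dynmod("taper must be non-negative, finite, somewhere positive, and match the window length",
                class = "dynmod_invalid_config")
  }
  taper <- taper / max(taper)
  structure(list(length = as.integer(length), step = as.integer(step),
                 taper = taper, taper_desc = taper_desc),
            class = "window_spec")
}

#' Smoothed rectangular taper
#'
#' A rectangular window of the requested length convolved with a truncated
#' Gaussian kernel (half-width 4 SD), cropped to the central `length` samples
#' and max-normalized. The flat interior keeps most samples at full weight
#' while the edges roll off smoothly.
#'
#' @param length taper length in time points.
#' @param sd Gaussian SD in time points.
#' @return numeric weight vector with maximum 1.
#' @export
taper_gaussian <- function(length, sd = 3) {
  stopifnot(is_count(length, 2), is_number(sd), sd > 0)
  half <- ceiling(4 * sd)
  kern <- exp(-0.5 * ((-half:half) / sd)^2)
  kern <- kern / sum(kern)
  full <- as.numeric(stats::convolve(rep(1, length), rev(kern), type = "open"))
  # central `length` samples: edges of the rectangle roll off over ~4 SD
  off <- (base::length(full) - length) %/% 2L
  w <- full[(off + 1L):(off + length)]
  w / max(w)
}

#' Plan sliding-window index ranges
#'
#' Windows are contiguous ranges of `spec$length` time points shifted by
#' `spec$step`; windows that would run past the end of the series are not
#' emitted, so the count is `floor((T - L) / s) + 1`.
#'
#' @param n_timepoints number of time points T.
#' @param spec a [window_spec()].
#' @return data.frame with 1-based inclusive `start` and `end` columns, one
#'   row per window.
#' @export
plan_windows <- function(n_timepoints, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (!is_count(n_timepoints, 1) || n_timepoints < spec$length) {
    stop_dynmod(sprintf("need at least %d time points, got %s", spec$length,
                        format(n_timepoints)),
                class = "dynmod_insufficient_data")
  }
  n_win <- (n_timepoints - spec$length) %/% spec$step + 1L
  start <- 1L + spec$step * (seq_len(n_win) - 1L)
  data.frame(start = start, end = start + spec$length - 1L)
}

#' Weighted Pearson correlation of two series
#'
#' Observation-weighted correlation: weighted means, weighted covariance and
#' weighted variances under the taper. With a uniform taper this is the
#' ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param taper non-negative weights with positive sum.
#' @return correlation in `[-1, 1]`; a pair with zero weighted variance
#'   yields 0 with a warning.
#' @export
weighted_correlation <- function(x, y, taper = rep(1, base::length(x))) {
  n <- base::length(x)
  if (base::length(y) != n || base::length(taper) != n) {
    stop_dynmod("x, y and taper must have equal length", class = "dynmod_invalid_config")
  }
  w <- taper / sum(taper)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("zero weighted variance; correlation set to 0")
    return(0)
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  clip(r, -1, 1)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`. Correlations within `1e-7` of +/-1 are clipped to
#' `+/-(1 - 1e-7)` before the transform (with a warning) so edge weights stay
#' finite.
#'
#' @param r correlation value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  if (any(abs(r) >= lim)) {
    warning("correlations at or beyond +/-(1 - 1e-7) clipped before Fisher transform")
    r <- clip(r, -lim, lim)
  }
  atanh(r)
}

# all pairwise weighted correlations of the columns of x under taper weights
weighted_corr_matrix <- function(x, taper) {
  w <- taper / sum(taper)
  xc <- sweep(x, 2, colSums(w * x), "-")
  cv <- crossprod(xc, w * xc) # weighted covariance (up to common factor)
  v <- diag(cv)
  zero <- v <= 0
  if (any(zero)) {
    warning(sprintf("%d node(s) with zero weighted variance; their edges set to 0",
                    sum(zero)))
    v[zero] <- 1
  }
  r <- cv / sqrt(outer(v, v))
  if (any(zero)) {
    r[zero, ] <- 0
    r[, zero] <- 0
  }
  r <- clip(r, -1, 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# one Fisher-z connectivity matrix from a (already sliced) window
window_connectivity_matrix <- function(slice, taper) {
  r <- weighted_corr_matrix(slice, taper)
  diag(r) <- 0
  z <- suppressWarnings(fisher_z(r)) # off-diagonal clipping is expected for near-duplicated nodes
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

#' Sliding-window Fisher-z connectivity stack
#'
#' One weighted, unthresholded, zero-diagonal symmetric matrix per planned
#' window.
#'
#' @param series a `parcellated_ts`.
#' @param spec a [window_spec()].
#' @return object of class `connectivity_stack`: list with `matrices`
#'   (node x node x window array), `windows` (the [plan_windows()] table),
#'   `spec`, and `subject_id`.
#' @export
connectivity_stack <- function(series, spec = window_spec()) {
  stopifnot(inherits(series, "parcellated_ts"), inherits(spec, "window_spec"))
  wins <- plan_windows(nrow(series$data), spec)
  n <- ncol(series$data)
  out <- array(0, dim = c(n, n, nrow(wins)),
               dimnames = list(series$node_ids, series$node_ids, NULL))
  for (k in seq_len(nrow(wins))) {
    slice <- series$data[wins$start[k]:wins$end[k], , drop = FALSE]
    out[, , k] <- window_connectivity_matrix(slice, spec$taper)
  }
  structure(list(matrices = out, windows = wins, spec = spec,
                 subject_id = series$subject_id),
            class = "connectivity_stack")
}

#' Static (full-scan) Fisher-z connectivity matrix
#'
#' Equivalent to a single uniform-taper window spanning the whole series.
#'
#' @param series a `parcellated_ts`.
#' @return node x node numeric matrix.
#' @export
static_connectivity <- function(series) {
  stopifnot(inherits(series, "parcellated_ts"))
  if (nrow(series$data) < 3L) {
    stop_dynmod("need at least 3 time points for a static correlation",
                class = "dynmod_insufficient_data")
  }
  window_connectivity_matrix(series$data, rep(1, nrow(series$data)))
}
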