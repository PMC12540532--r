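# Trace-level signal primitives: zero-phase Butterworth smoothing,
# three-point differentiation, event detection and peak location.

#' Low-pass filter specification
#'
#' @param order Butterworth order (default 4).
#' @param cutoff Cut-off frequency in Hz (default 14, the convention for
#'   human lifting-force records).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4, cutoff = 14) {
  stopifnot(is_count(order), is.numeric(cutoff), cutoff > 0)
  structure(list(order = as.integer(order), cutoff = cutoff),
            class = "filter_spec")
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies an `order`-th order Butterworth low-pass filter forward and then
#' backward, giving zero phase lag and a squared magnitude response
#' \deqn{|H(f)|^2 = 1 / (1 + (f/f_c)^{2 \cdot order}).}
#' Edges are handled by odd-reflection padding with steady-state initial
#' conditions, so a constant signal is returned exactly unchanged (DC gain 1)
#' and edge transients do not leak into the output.
#'
#' @param x Numeric series, uniformly sampled.
#' @param sampling_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @export
lowpass_zero_phase <- function(x, sampling_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), sampling_rate > 0)
  if (spec$cutoff >= sampling_rate / 2) {
    stop("filter cutoff (", spec$cutoff, " Hz) must be below the Nyquist ",
         "frequency ", sampling_rate / 2, " Hz", call. = FALSE)
  }
  padlen <- 3L * (spec$order + 1L)
  n <- length(x)
  if (n <= padlen) {
    stop("signal too short for zero-phase filtering: need more than ",
         padlen, " samples, got ", n, call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$cutoff / (sampling_rate / 2),
                       type = "low")
  # odd reflection about the end points suppresses edge transients
  pre  <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xx <- c(pre, x, post)
  y <- iir_filter(bt$b, bt$a, xx)
  y <- rev(iir_filter(bt$b, bt$a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# One-directional IIR pass with steady-state handling of the left boundary:
# the filter is applied to (x - x[1]) from rest and x[1] is added back.
# Because the Butterworth DC gain is 1, this equals seeding the filter state
# as if the input had been x[1] forever, so constants pass through exactly.
# Both passes run in C via stats::filter.
iir_filter <- function(b, a, x) {
  x0 <- x[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x - x0), b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  y <- stats::filter(v, -a[-1L], method = "recursive")
  as.numeric(y) + x0
}

#' Three-point central-difference differentiation
#'
#' Interior samples use `(x[i+1] - x[i-1]) * rate / 2` (exact for
#' polynomials up to degree 2); the two boundary samples use one-sided first
#' differences so output length equals input length.
#'
#' @param x Numeric series.
#' @param sampling_rate Sampling rate in Hz.
#' @return Derivative series in units/second, same length as `x`.
#' @export
differentiate <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 3L) stop("differentiation needs at least 3 samples", call. = FALSE)
  d <- numeric(n)
  d[2L:(n - 1L)] <- (x[3L:n] - x[1L:(n - 2L)]) * sampling_rate / 2
  d[1L] <- (x[2L] - x[1L]) * sampling_rate
  d[n]  <- (x[n] - x[n - 1L]) * sampling_rate
  d
}

#' Detect force onset by threshold crossing
#'
#' Returns the time (seconds, sample 1 at t = 0) of the first sample
#' *strictly* exceeding `threshold`, or `NA` if it is never exceeded.
#'
#' @param x Force series in newtons.
#' @param sampling_rate Hz.
#' @param threshold Newtons (> 0); the handle convention is 0.2 N of load
#'   force, the platform convention 0.4 N of force reduction.
#' @return Onset time in seconds, or `NA_real_`.
#' @export
detect_onset <- function(x, sampling_rate, threshold) {
  stopifnot(threshold > 0)
  idx <- which(x > threshold)
  if (length(idx) == 0L) return(NA_real_)
  (idx[1L] - 1L) / sampling_rate
}

#' Detect lift-off from a photogate channel
#'
#' @param photogate Logical (or 0/1) series, `TRUE` once the object has left
#'   the surface.
#' @param sampling_rate Hz.
#' @return Time of the first `TRUE` sample in seconds, or `NA_real_`.
#' @export
detect_liftoff <- function(photogate, sampling_rate) {
  idx <- which(as.logical(photogate))
  if (length(idx) == 0L) return(NA_real_)
  (idx[1L] - 1L) / sampling_rate
}

# Convert a [start, end] time window (seconds) to sample indices; sample 1 is
# t = 0.  Errors on an empty window.
window_indices <- function(n, sampling_rate, start_time, end_time) {
  i0 <- max(1L, as.integer(ceiling(round(start_time * sampling_rate, 9))) + 1L)
  i1 <- min(n, as.integer(floor(round(end_time * sampling_rate, 9))) + 1L)
  if (is.na(i0) || is.na(i1) || i0 > i1) {
    stop("empty search window [", start_time, ", ", end_time, "] s",
         call. = FALSE)
  }
  i0:i1
}

#' Global maximum in a time window
#'
#' @param x Numeric series.
#' @param sampling_rate Hz.
#' @param start_time,end_time Window in seconds (inclusive); sample 1 is t = 0.
#' @return List with `value` and `time` (first occurrence on ties).
#' @export
find_global_peak <- function(x, sampling_rate, start_time = 0,
                             end_time = (length(x) - 1) / sampling_rate) {
  idx <- window_indices(length(x), sampling_rate, start_time, end_time)
  j <- idx[which.max(x[idx])]
  list(value = x[j], time = (j - 1L) / sampling_rate)
}

#' First prominent local maximum of a rate series
#'
#' Locates the first local maximum within a time window whose topographic
#' prominence is at least `min_prominence` times the window maximum.  This
#' automates the rater's "first peak in force rate" selection: small noise
#' ripples are rejected by the prominence floor, and a series still rising at
#' the window end (the truncation case near lift-off) has no qualifying peak,
#' returning absence rather than an error.
#'
#' The window constrains where the peak may *lie*; prominence is a
#' topographic property of the peak within the whole recorded series, so its
#' bases are sought over the full series.  (A window edge that happens to cut
#' a peak mid-rise must not erase the peak's prominence: detection windows
#' are analysis choices, not data boundaries.)
#'
#' @param x Rate series (the full recording).
#' @param sampling_rate Hz.
#' @param start_time,end_time Search window in seconds.
#' @param min_prominence Fraction of the window maximum (default 0.05).
#' @return List with `value` and `time`, or `NULL` when no local maximum
#'   qualifies.
#' @export
find_first_rate_peak <- function(x, sampling_rate, start_time, end_time,
                                 min_prominence = 0.05) {
  idx <- window_indices(length(x), sampling_rate, start_time, end_time)
  n <- length(x)
  if (n < 3L) return(NULL)
  # interior local maxima of the series; plateaus credited to their first
  # sample
  cand <- which(x[2L:(n - 1L)] >= x[1L:(n - 2L)] &
                  x[2L:(n - 1L)] > x[3L:n]) + 1L
  if (length(cand) > 1L) {
    keep <- c(TRUE, !(diff(cand) == 1L & x[cand[-length(cand)]] ==
                        x[cand[-1L]]))
    cand <- cand[keep]
  }
  cand <- cand[cand %in% idx]
  floor_val <- min_prominence * max(x[idx])
  for (j in cand) {
    if (peak_prominence(x, j) >= floor_val) {
      return(list(value = x[j], time = (j - 1L) / sampling_rate))
    }
  }
  NULL
}

# Topographic prominence of w[j] within the window: on each side, the minimum
# between the peak and the nearest strictly higher sample (or the window
# edge); prominence = height minus the larger of the two minima.
peak_prominence <- function(w, j) {
  h <- w[j]
  left <- if (j == 1L) h else {
    higher <- which(w[1L:(j - 1L)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(w[lo:(j - 1L)])
  }
  right <- if (j == length(w)) h else {
    higher <- which(w[(j + 1L):length(w)] > h)
    hi <- if (length(higher)) j + min(higher) - 1L else length(w)
    min(w[(j + 1L):hi])
  }
  h - max(left, right)
}
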