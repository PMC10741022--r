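#' Step-forward spike encoding parameters
#'
#' Controls how real-valued series become ternary spike trains.  The encoder
#' tracks a running baseline `B` per series: a `+1` spike is emitted (and
#' `B <- B + theta`) when the signal reaches `B + theta`, a `-1` spike (and
#' `B <- B - theta`) when it falls to `B - theta`, else `0`.  Values exactly at
#' `B +/- theta` emit a spike.
#'
#' @param spike_threshold Positive threshold `theta`, in normalized signal
#'   units when `normalize = TRUE` (default 0.5).
#' @param window_size Smoothing window width in time steps (default 5).
#' @param filter_type `"moving_average"` (default) or `"none"`.
#' @param normalize Min-max rescale each series to `[0, 1]` per sample and
#'   variable before filtering (default `TRUE`). A constant series maps to
#'   constant 0.
#' @return An `encoder_params` list.
#' @export
encoder_params <- function(spike_threshold = 0.5, window_size = 5L,
                           filter_type = c("moving_average", "none"),
                           normalize = TRUE) {
  filter_type <- match.arg(filter_type)
  if (!is.numeric(spike_threshold) || length(spike_threshold) != 1L ||
      spike_threshold <= 0) {
    abort("`spike_threshold` must be a single positive number.")
  }
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) {
    abort("`window_size` must be an integer >= 1.")
  }
  structure(list(spike_threshold = spike_threshold,
                 window_size = window_size,
                 filter_type = filter_type,
                 normalize = isTRUE(normalize)),
            class = "encoder_params")
}

#' Centered moving-average filter
#'
#' Smooths a series with a centered window of width `window`, clipped at the
#' boundaries (boundary means are taken over the available points).
#'
#' @param signal Numeric vector.
#' @param window Integer window width, `1 <= window <= length(signal)`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' moving_average_filter(c(0, 1, 0, 1, 0), 3)
moving_average_filter <- function(signal, window) {
  if (length(signal) == 0L) abort("`signal` must be non-empty.")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) abort("`window` must be >= 1.")
  if (window > length(signal)) abort("`window` exceeds the signal length.")
  if (window == 1L) return(as.numeric(signal))
  n <- length(signal)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(c(0, signal))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Normalize to [0,1]; a zero range maps to constant 0.
minmax01 <- function(x) {
  r <- range(x)
  if (r[2L] - r[1L] == 0) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

# Filter + optional normalization applied before threshold encoding.
preprocess_series <- function(x, params) {
  if (params$normalize) x <- minmax01(x)
  if (params$filter_type == "moving_average" && params$window_size > 1L) {
    x <- moving_average_filter(x, min(params$window_size, length(x)))
  }
  x
}

# Step-forward encode one preprocessed series; first step carries no spike
# because the baseline initializes to the first value.
sf_encode_series <- function(x, theta) {
  n <- length(x)
  pol <- integer(n)
  b <- x[1L]
  if (n > 1L) {
    for (t in 2:n) {
      if (x[t] >= b + theta) {
        pol[t] <- 1L
        b <- b + theta
      } else if (x[t] <= b - theta) {
        pol[t] <- -1L
        b <- b - theta
      }
    }
  }
  pol
}

#' Encode a sample set into ternary spike trains
#'
#' Applies optional min-max normalization and smoothing per (sample, variable)
#' series, then threshold (step-forward) encoding.  The returned object keeps
#' the per-series initial baselines and the filtered signals so the encoding
#' is invertible up to the spike threshold (see [step_forward_decode()]).
#'
#' @param x A [sample_set()].
#' @param params An [encoder_params()].
#' @return A `spike_train_set`: ternary `polarity` array shaped like
#'   `x$values`, `initial_baseline` (samples x variables), the filtered
#'   signals, and the encoder parameters.
#' @export
step_forward_encode <- function(x, params = encoder_params()) {
  stopifnot(inherits(x, "sample_set"), inherits(params, "encoder_params"))
  d <- dim(x)
  pol <- array(0L, d, dimnames = dimnames(x$values))
  filt <- array(0, d, dimnames = dimnames(x$values))
  base <- matrix(0, d[1L], d[2L], dimnames = list(NULL, x$variable_names))
  for (i in seq_len(d[1L])) {
    for (v in seq_len(d[2L])) {
      f <- preprocess_series(x$values[i, v, ], params)
      filt[i, v, ] <- f
      base[i, v] <- f[1L]
      pol[i, v, ] <- sf_encode_series(f, params$spike_threshold)
    }
  }
  structure(
    list(polarity = pol, initial_baseline = base, filtered = filt,
         params = params, labels = x$labels, coordinates = x$coordinates,
         variable_names = x$variable_names),
    class = "spike_train_set"
  )
}

#' @export
dim.spike_train_set <- function(x) dim(x$polarity)

#' @export
print.spike_train_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<spike_train_set> %d samples x %d variables x %d time steps (theta = %g)\n",
    d[1L], d[2L], d[3L], x$params$spike_threshold))
  cat(sprintf("  spike density: %.3f (+), %.3f (-)\n",
              mean(x$polarity == 1L), mean(x$polarity == -1L)))
  invisible(x)
}

#' Reconstruct signals from a spike train set
#'
#' Inverts step-forward encoding: each reconstructed series is
#' `baseline + theta * cumsum(polarity)`.  The reconstruction tracks the
#' filtered, normalized signal to within `theta` at every time point whenever
#' the filtered signal moves by at most `theta` per step (always true under
#' the default normalize + window-5 + `theta = 0.5` settings).
#'
#' @param spikes A `spike_train_set` from [step_forward_encode()].
#' @return A [sample_set()] of reconstructed (filtered-scale) signals.
#' @export
step_forward_decode <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(spikes$initial_baseline)) {
    abort("spike train set carries no initial baselines; cannot decode.")
  }
  d <- dim(spikes)
  theta <- spikes$params$spike_threshold
  rec <- array(0, d, dimnames = dimnames(spikes$polarity))
  for (i in seq_len(d[1L])) {
    for (v in seq_len(d[2L])) {
      rec[i, v, ] <- spikes$initial_baseline[i, v] +
        theta * cumsum(spikes$polarity[i, v, ])
    }
  }
  sample_set(rec, labels = spikes$labels, coordinates = spikes$coordinates,
             variable_names = spikes$variable_names)
}
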