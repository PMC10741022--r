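#' Synthetic EEG-like sample sets
#'
#' Generates labelled oscillatory multichannel data shaped like a small
#' motor-task EEG study: each sample is a class-specific oscillation on the
#' informative channels plus a shared slow background drift and white noise.
#' Class identity is injected as a *frequency* offset (`effect` scales the
#' offset), which survives per-series min-max normalization, unlike a mean
#' offset.  Channel coordinates lie on two scalp-like rings lifted onto a
#' unit sphere.
#'
#' @param n_samples Total samples (default 60, balanced over classes).
#' @param n_variables Channels (default 14).
#' @param n_time Time points per sample (default 128).
#' @param n_classes Classes (default 3).
#' @param informative_variables Channel indices carrying the class signal
#'   (default: all channels).
#' @param effect Class separation, >= 0; scales the inter-class frequency
#'   offset (0 makes classes indistinguishable).
#' @param noise_sd White-noise standard deviation (default 0.2).
#' @param seed RNG seed (required for reproducibility).
#' @return A [sample_set()]; the informative channel indices are attached as
#'   attribute `"informative"`.
#' @export
gen_eeg <- function(n_samples = 60L, n_variables = 14L, n_time = 128L,
                    n_classes = 3L, informative_variables = NULL,
                    effect = 1, noise_sd = 0.2, seed = 1L) {
  if (n_classes < 2L) abort("`n_classes` must be >= 2.")
  if (effect < 0 || noise_sd < 0) abort("`effect` and `noise_sd` must be >= 0.")
  informative_variables <- informative_variables %||% seq_len(n_variables)
  if (any(informative_variables > n_variables)) {
    abort("`informative_variables` must index existing variables.")
  }
  labels <- rep_len(seq_len(n_classes), n_samples)[order(rep_len(
    seq_len(n_classes), n_samples))]          # blocks: 1..1, 2..2, ...
  tt <- seq_len(n_time) / n_time
  base_freq <- 4
  vals <- array(0, c(n_samples, n_variables, n_time))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_samples)) {
      bg <- 0.3 * sin(2 * pi * 1.5 * tt + stats::runif(1, 0, 2 * pi))
      for (v in seq_len(n_variables)) {
        f <- base_freq +
          if (v %in% informative_variables) 2 * effect * (labels[i] - 1) else 0
        phase <- stats::runif(1, 0, 2 * pi)
        vals[i, v, ] <- sin(2 * pi * f * tt + phase) + bg +
          stats::rnorm(n_time, sd = noise_sd)
      }
    }
  })
  out <- sample_set(vals, labels = paste0("class", labels),
                    coordinates = eeg_ring_coordinates(n_variables),
                    variable_names = paste0("ch", seq_len(n_variables)))
  attr(out, "informative") <- informative_variables
  out
}

#' Scalp-like channel coordinates
#'
#' Places channels on two concentric rings lifted onto the unit sphere (outer
#' ring first), approximating a reduced electrode montage.
#'
#' @param n Number of channels.
#' @return `n x 3` coordinate matrix.
#' @export
eeg_ring_coordinates <- function(n) {
  n_outer <- ceiling(n * 8 / 14)
  n_inner <- n - n_outer
  ring <- function(k, r, offset = 0) {
    if (k == 0L) return(matrix(numeric(0), 0, 3))
    a <- 2 * pi * (seq_len(k) - 1) / k + offset
    cbind(r * cos(a), r * sin(a), sqrt(pmax(1 - r^2, 0)))
  }
  co <- rbind(ring(n_outer, 0.9), ring(n_inner, 0.5, offset = pi / 8))
  colnames(co) <- c("x", "y", "z")
  co
}

# Canonical double-gamma hemodynamic response sampled at `times` (seconds),
# peak normalized to 1.
hrf_double_gamma <- function(times) {
  h <- stats::dgamma(times, shape = 6, rate = 1) -
    stats::dgamma(times, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Synthetic fMRI-like sample sets
#'
#' Generates two-class slow hemodynamic data shaped like a short
#' sentence-reading fMRI study: each trial spans `n_time` volumes over an
#' 8-second window; informative voxels carry a hemodynamic-response-shaped
#' signal whose amplitude differs between the classes by `effect`,
#' uninformative voxels are pure noise.  Voxels sit on a 3D grid.
#'
#' @param n_samples Total trials (default 40, balanced over the 2 classes).
#' @param n_variables Voxels (default 200 — a desk-scale stand-in for a
#'   whole-brain voxel set).
#' @param n_time Volumes per trial (default 16).
#' @param n_informative Number of informative voxels (default 20; the first
#'   `n_informative` voxel indices).
#' @param effect Amplitude difference between classes on informative voxels.
#' @param noise_sd Noise standard deviation (default 0.5).
#' @param seed RNG seed.
#' @param trial_seconds Trial duration spanned by the `n_time` volumes.
#' @return A [sample_set()] with 2 classes; informative voxel indices in
#'   attribute `"informative"`.
#' @export
gen_fmri <- function(n_samples = 40L, n_variables = 200L, n_time = 16L,
                     n_informative = 20L, effect = 1, noise_sd = 0.5,
                     seed = 1L, trial_seconds = 8) {
  if (n_informative > n_variables) {
    abort("`n_informative` cannot exceed `n_variables`.")
  }
  labels <- rep_len(1:2, n_samples)[order(rep_len(1:2, n_samples))]
  times <- seq(0, trial_seconds, length.out = n_time + 1L)[-1L]
  h <- hrf_double_gamma(times)
  base_amp <- 0.5
  vals <- array(0, c(n_samples, n_variables, n_time))
  withr::with_seed(as.integer(seed), {
    noise <- array(stats::rnorm(length(vals), sd = noise_sd), dim(vals))
    for (i in seq_len(n_samples)) {
      amp <- base_amp + effect * (labels[i] - 1)
      for (v in seq_len(n_informative)) {
        vals[i, v, ] <- amp * h
      }
    }
  })
  vals <- vals + noise
  side <- ceiling(n_variables^(1 / 3))
  grid <- grid_template(side, side, side)$coordinates[seq_len(n_variables), ]
  out <- sample_set(vals, labels = paste0("class", labels),
                    coordinates = grid,
                    variable_names = paste0("vox", seq_len(n_variables)))
  attr(out, "informative") <- seq_len(n_informative)
  out
}
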