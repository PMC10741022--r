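# Shared fixtures, built in code.

# sample_set from a variables x time matrix (single sample)
one_sample_set <- function(m, label = "a") {
  v <- nrow(m)
  sample_set(array(m, c(1L, v, ncol(m))), labels = label,
             coordinates = matrix(seq_len(3L * v), v, 3L))
}

raw_encoder <- function(theta = 0.5) {
  encoder_params(spike_threshold = theta, filter_type = "none",
                 normalize = FALSE)
}

# spike_raster from a neurons x time logical matrix
make_raster <- function(fired) {
  fs <- apply(fired, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  structure(list(fired = fired, first_spike_time = as.integer(fs)),
            class = "spike_raster")
}

# a cube with hand-set connections (bypasses random wiring)
hand_cube <- function(n, pre, post, weight, lif = lif_params(),
                      stdp = stdp_params(), input_map = c(V1 = 1L),
                      input_gain = 1) {
  co <- cbind(seq_len(n), 0, 0)
  cube <- new_snn_cube(neuron_template(co), lif = lif, stdp = stdp,
                       input_gain = input_gain, input_map = input_map)
  m <- length(pre)
  cube$pre <- as.integer(pre)
  cube$post <- as.integer(post)
  cube$weight <- as.numeric(weight)
  cube$sign <- as.integer(sign(weight) + (weight == 0))
  cube$in_conn <- split(seq_len(m), factor(cube$post, levels = seq_len(n)))
  cube$out_conn <- split(seq_len(m), factor(cube$pre, levels = seq_len(n)))
  cube$sw <- small_world_params(seed = 1L)
  cube
}

# spike_train_set carrying an explicit polarity array
hand_spikes <- function(pol, theta = 0.5) {
  d <- dim(pol)
  vn <- paste0("V", seq_len(d[2L]))
  dimnames(pol) <- list(NULL, vn, NULL)
  structure(
    list(polarity = pol, initial_baseline = matrix(0, d[1L], d[2L]),
         filtered = array(0, d), params = encoder_params(theta),
         labels = factor(rep("a", d[1L])),
         coordinates = matrix(seq_len(3L * d[2L]), d[2L], 3L),
         variable_names = vn),
    class = "spike_train_set"
  )
}

# Accuracy-bearing fixtures keep the reference 128-step window: the default
# window-5 smoother attenuates the fastest class oscillation when the window
# is shortened much below that.
tiny_eeg <- function(n = 12L, t = 128L, seed = 42L, effect = 1) {
  gen_eeg(n_samples = n, n_time = t, seed = seed, effect = effect)
}

tiny_config <- function(seed = 42L, dims = 4L) {
  stam_config(seed = seed,
              template = list(nx = dims, ny = dims, nz = dims))
}
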