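#' Reservoir parameter sets
#'
#' Constructors for the parameter bundles of the 3D spiking reservoir:
#' small-world wiring, leaky integrate-and-fire (LIF) dynamics, and
#' spike-timing-dependent plasticity (STDP).  Defaults reproduce the reference
#' EEG configuration (leak 0.002, firing threshold 0.5, refractory 6 steps,
#' STDP rate 0.01, one training iteration, no long-distance connections).
#'
#' @param C Scale of the distance-decaying connection probability, in (0, 1].
#' @param lambda Length scale of the probability decay (same units as the
#'   template coordinates).
#' @param max_distance Hard wiring cutoff radius, or `NULL` for none.  Pairs
#'   beyond the cutoff connect with probability `ldc_probability`.
#' @param inhibitory_fraction Probability that a neuron is inhibitory (all its
#'   outgoing weights negative).
#' @param ldc_probability Long-distance connection probability (default 0).
#' @param w0 Upper bound of the initial weight magnitudes, drawn uniform on
#'   `(0, w0]`.
#' @param seed Integer RNG seed; required (unseeded wiring is an error).
#' @return A parameter list of the corresponding class.
#' @export
small_world_params <- function(C = 1, lambda = 2.5, max_distance = 3,
                               inhibitory_fraction = 0.2,
                               ldc_probability = 0, w0 = 0.1, seed = NULL) {
  if (!(C > 0 && C <= 1)) abort("`C` must lie in (0, 1].")
  if (!(lambda > 0)) abort("`lambda` must be positive.")
  if (!is.null(max_distance) && max_distance <= 0) {
    abort("`max_distance` must be positive or NULL.")
  }
  if (inhibitory_fraction < 0 || inhibitory_fraction >= 1) {
    abort("`inhibitory_fraction` must lie in [0, 1).")
  }
  if (ldc_probability < 0 || ldc_probability > 1) {
    abort("`ldc_probability` must lie in [0, 1].")
  }
  if (!(w0 > 0)) abort("`w0` must be positive.")
  structure(list(C = C, lambda = lambda, max_distance = max_distance,
                 inhibitory_fraction = inhibitory_fraction,
                 ldc_probability = ldc_probability, w0 = w0, seed = seed),
            class = "small_world_params")
}

#' @rdname small_world_params
#' @param firing_threshold Membrane potential at which a neuron fires.
#' @param leak_rate Multiplicative potential leak per step, in `[0, 1)`:
#'   `u <- u * (1 - leak_rate)`.
#' @param refractory_time Steps after a spike during which the neuron neither
#'   integrates nor fires.
#' @export
lif_params <- function(firing_threshold = 0.5, leak_rate = 0.002,
                       refractory_time = 6L) {
  if (!(firing_threshold > 0)) abort("`firing_threshold` must be positive.")
  if (leak_rate < 0 || leak_rate >= 1) abort("`leak_rate` must lie in [0, 1).")
  refractory_time <- as.integer(refractory_time)
  if (is.na(refractory_time) || refractory_time < 0L) {
    abort("`refractory_time` must be an integer >= 0.")
  }
  structure(list(firing_threshold = firing_threshold, leak_rate = leak_rate,
                 refractory_time = refractory_time),
            class = "lif_params")
}

#' @rdname small_world_params
#' @param a_plus,a_minus Potentiation / depression amplitudes (both >= 0; the
#'   reference "STDP rate" 0.01 sets both).
#' @param tau_plus,tau_minus Decay time constants, in time steps.
#' @param iterations Unsupervised training passes over the whole sample
#'   sequence.
#' @param w_max Weight magnitude clip during learning.
#' @export
stdp_params <- function(a_plus = 0.01, a_minus = 0.01,
                        tau_plus = 10, tau_minus = 10,
                        iterations = 1L, w_max = 1) {
  if (a_plus < 0 || a_minus < 0) abort("STDP amplitudes must be >= 0.")
  if (tau_plus <= 0 || tau_minus <= 0) abort("STDP time constants must be positive.")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) abort("`iterations` must be >= 1.")
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, iterations = iterations, w_max = w_max),
            class = "stdp_params")
}

#' Distance-decaying connection probability
#'
#' Probability that two neurons at Euclidean distance `d` are connected under
#' the small-world wiring rule, `min(1, C * exp(-d^2 / lambda^2))`.
#'
#' @param d Distance(s).
#' @param C Scale in (0, 1].
#' @param lambda Length scale.
#' @return Probability in `[0, 1]`, vectorized over `d`.
#' @export
#' @examples
#' connection_probability(1, C = 1, lambda = 1)  # exp(-1)
connection_probability <- function(d, C, lambda) {
  pmin(1, C * exp(-(d^2) / lambda^2))
}

#' Construct an unconnected spiking reservoir
#'
#' @param template A `neuron_template`.
#' @param lif [lif_params()].
#' @param stdp [stdp_params()].
#' @param input_gain Current injected per input spike (so one spike fires the
#'   mapped neuron under the default 0.5 threshold).
#' @param input_map Optional named neuron index per variable (see
#'   [map_inputs()]).
#' @return An `snn_cube` without connections; wire it with
#'   [init_small_world()].
#' @export
new_snn_cube <- function(template, lif = lif_params(), stdp = stdp_params(),
                         input_gain = 1, input_map = NULL) {
  stopifnot(inherits(template, "neuron_template"),
            inherits(lif, "lif_params"), inherits(stdp, "stdp_params"))
  n <- nrow(template$coordinates)
  if (!is.null(input_map)) check_input_map(input_map, n)
  structure(
    list(template = template, n_neurons = n,
         pre = integer(0), post = integer(0),
         weight = numeric(0), sign = integer(0),
         in_conn = rep(list(integer(0)), n),
         out_conn = rep(list(integer(0)), n),
         input_map = input_map, input_gain = input_gain,
         lif = lif, stdp = stdp, sw = NULL, trained = FALSE),
    class = "snn_cube"
  )
}

check_input_map <- function(input_map, n) {
  if (anyDuplicated(input_map) > 0L) abort("`input_map` must be injective.")
  if (any(input_map < 1L | input_map > n)) abort("`input_map` indexes outside the template.")
  if (is.null(names(input_map))) abort("`input_map` must be named by variable.")
  invisible(input_map)
}

#' Assign the variable-to-neuron input mapping
#'
#' @param cube An `snn_cube`.
#' @param input_map Named integer vector (see [map_inputs()]).
#' @return The cube with the mapping set.
#' @export
set_input_map <- function(cube, input_map) {
  stopifnot(inherits(cube, "snn_cube"))
  check_input_map(input_map, cube$n_neurons)
  cube$input_map <- input_map
  cube
}

#' @export
print.snn_cube <- function(x, ...) {
  cat(sprintf("<snn_cube> %d neurons, %d connections%s%s\n",
              x$n_neurons, length(x$weight),
              if (x$trained) ", trained" else "",
              if (is.null(x$input_map)) "" else
                sprintf(", %d inputs", length(x$input_map))))
  invisible(x)
}

#' Wire a reservoir with small-world connectivity
#'
#' Every ordered neuron pair (a, b), a != b, within `max_distance` receives a
#' directed connection with probability `C * exp(-d^2 / lambda^2)`; pairs
#' beyond the cutoff connect with probability `ldc_probability`.  Each neuron
#' is inhibitory with probability `inhibitory_fraction` (all outgoing weights
#' negative); initial magnitudes are uniform on `(0, w0]`.
#'
#' @param cube An `snn_cube` from [new_snn_cube()].
#' @param params [small_world_params()] carrying a non-`NULL` seed.
#' @return The wired cube.
#' @export
init_small_world <- function(cube, params) {
  stopifnot(inherits(cube, "snn_cube"), inherits(params, "small_world_params"))
  if (is.null(params$seed)) {
    abort("small-world wiring requires an explicit `seed` (reproducibility contract).")
  }
  co <- cube$template$coordinates
  n <- nrow(co)
  d2 <- as.matrix(stats::dist(co))^2
  p <- matrix(connection_probability(sqrt(d2), params$C, params$lambda), n, n)
  if (!is.null(params$max_distance)) {
    p[d2 > params$max_distance^2] <- params$ldc_probability
  }
  diag(p) <- 0
  withr::with_seed(as.integer(params$seed), {
    conn <- matrix(stats::runif(n * n) < p, n, n)
    inhibitory <- stats::runif(n) < params$inhibitory_fraction
    idx <- which(conn, arr.ind = TRUE)   # row = pre (a), col = post (b)
    m <- nrow(idx)
    mag <- params$w0 * (1 - stats::runif(m))  # uniform on (0, w0]
  })
  sgn <- ifelse(inhibitory[idx[, 1L]], -1L, 1L)
  cube$pre <- idx[, 1L]
  cube$post <- idx[, 2L]
  cube$sign <- as.integer(sgn)
  cube$weight <- mag * sgn
  cube$in_conn <- split(seq_len(m), factor(cube$post, levels = seq_len(n)))
  cube$out_conn <- split(seq_len(m), factor(cube$pre, levels = seq_len(n)))
  cube$sw <- params
  cube$trained <- FALSE
  cube
}

#' Pairwise STDP weight change
#'
#' Signed weight change for one pre/post spike pair: potentiation
#' `a_plus * exp((t_pre - t_post) / tau_plus)` when the pre-synaptic spike
#' precedes the post-synaptic one, depression
#' `-a_minus * exp(-(t_pre - t_post) / tau_minus)` when it follows, and 0 for
#' simultaneous spikes.
#'
#' @param t_pre,t_post Spike times (time steps).
#' @param params [stdp_params()].
#' @return Signed weight change.
#' @export
#' @examples
#' stdp_delta(0, 10, stdp_params(a_plus = 0.01, tau_plus = 10))  # 0.01 * exp(-1)
stdp_delta <- function(t_pre, t_post, params = stdp_params()) {
  stopifnot(inherits(params, "stdp_params"))
  dt <- t_pre - t_post
  ifelse(dt < 0, params$a_plus * exp(dt / params$tau_plus),
         ifelse(dt > 0, -params$a_minus * exp(-dt / params$tau_minus), 0))
}

# Core discrete-time LIF + STDP engine for one sample.
# pol: variables x time integer matrix of input polarities (rows named).
# Returns list(fired = neurons x time logical, weight = updated weights).
run_cube <- function(cube, pol, learn = FALSE) {
  n <- cube$n_neurons
  Tn <- ncol(pol)
  if (Tn < 1L) abort("spike train has length 0.")
  if (is.null(cube$input_map)) abort("cube has no input map.")
  vars <- rownames(pol)
  if (!all(vars %in% names(cube$input_map))) {
    missing <- setdiff(vars, names(cube$input_map))
    abort(paste0("variables not covered by the input map: ",
                 paste(missing, collapse = ", ")))
  }
  in_neuron <- cube$input_map[vars]
  lif <- cube$lif
  st <- cube$stdp
  w <- cube$weight
  mag <- abs(w)
  sgn <- cube$sign
  u <- numeric(n)
  refrac <- integer(n)
  prev_fired <- integer(0)
  last_spike <- rep(-Inf, n)
  fired_mat <- matrix(FALSE, n, Tn)
  for (t in seq_len(Tn)) {
    refrac <- pmax(refrac - 1L, 0L)
    u <- u * (1 - lif$leak_rate)
    # external drive at this step
    polt <- pol[, t]
    nz <- which(polt != 0L)
    if (length(nz)) {
      u[in_neuron[nz]] <- u[in_neuron[nz]] + cube$input_gain * polt[nz]
    }
    # recurrent drive from last step's spikes (one-step transmission)
    if (length(prev_fired)) {
      cids <- unlist(cube$out_conn[prev_fired], use.names = FALSE)
      if (length(cids)) {
        agg <- rowsum(w[cids], cube$post[cids])
        tgt <- as.integer(rownames(agg))
        u[tgt] <- u[tgt] + agg[, 1L]
      }
    }
    u[refrac > 0L] <- 0      # refractory neurons do not integrate
    fired <- which(refrac == 0L & u >= lif$firing_threshold)
    if (length(fired)) {
      u[fired] <- 0
      # counter decrements at step start, so the neuron is silent for the
      # next refractory_time steps and eligible again at t + refractory + 1
      refrac[fired] <- lif$refractory_time + 1L
      fired_mat[fired, t] <- TRUE
    }
    if (learn && length(fired)) {
      # nearest-spike pairing against the most recent spike before step t
      pot <- unlist(cube$in_conn[fired], use.names = FALSE)
      if (length(pot)) {
        tp <- last_spike[cube$pre[pot]]
        ok <- is.finite(tp)
        if (any(ok)) {
          pot <- pot[ok]
          dw <- st$a_plus * exp((tp[ok] - t) / st$tau_plus)
          mag[pot] <- mag[pot] + dw
        }
      }
      dep <- unlist(cube$out_conn[fired], use.names = FALSE)
      if (length(dep)) {
        tq <- last_spike[cube$post[dep]]
        ok <- is.finite(tq)
        if (any(ok)) {
          dep <- dep[ok]
          dw <- st$a_minus * exp(-(t - tq[ok]) / st$tau_minus)
          mag[dep] <- mag[dep] - dw
        }
      }
      mag <- pmin(pmax(mag, 0), st$w_max)
      w <- mag * sgn
    }
    if (length(fired)) last_spike[fired] <- t
    prev_fired <- fired
  }
  list(fired = fired_mat, weight = w)
}

new_spike_raster <- function(fired) {
  fs <- apply(fired, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  structure(list(fired = fired, first_spike_time = as.integer(fs)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d steps, %d spikes (%d active neurons)\n",
              nrow(x$fired), ncol(x$fired), sum(x$fired),
              sum(!is.na(x$first_spike_time))))
  invisible(x)
}

# variables x time polarity matrix for one sample
sample_polarity <- function(spikes, sample_index) {
  m <- spikes$polarity[sample_index, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(spikes)[2L])
  rownames(m) <- spikes$variable_names
  m
}

#' Simulate the reservoir on one encoded sample
#'
#' Runs the discrete-time LIF loop: input spikes inject `polarity x input_gain`
#' into their mapped neurons, recurrent spikes arrive one step later, the
#' membrane leaks multiplicatively, and a neuron fires on reaching the
#' threshold, then resets and observes its refractory period.  With
#' `learn = TRUE` STDP is applied after every step and the updated cube is
#' attached to the result as attribute `"cube"`.
#'
#' @param cube A wired `snn_cube` with an input map.
#' @param spikes A `spike_train_set`.
#' @param sample_index Which sample to present.
#' @param learn Apply STDP while simulating (default `FALSE` = pure recall).
#' @return A `spike_raster` (fired matrix + first spike time per neuron).
#' @export
simulate_cube <- function(cube, spikes, sample_index, learn = FALSE) {
  stopifnot(inherits(cube, "snn_cube"), inherits(spikes, "spike_train_set"))
  res <- run_cube(cube, sample_polarity(spikes, sample_index), learn = learn)
  raster <- new_spike_raster(res$fired)
  if (learn) {
    cube$weight <- res$weight
    attr(raster, "cube") <- cube
  }
  raster
}

#' Unsupervised STDP training of the reservoir
#'
#' Presents every sample in order (for `iterations` passes over the whole
#' sequence) with STDP learning on.  Weight changes persist across samples:
#' the wired structure acts as the model's long-term memory.
#'
#' @param cube A wired `snn_cube` with an input map.
#' @param spikes A `spike_train_set` of the full training data.
#' @param iterations Training passes (defaults to the cube's STDP setting).
#' @return The trained cube (`trained = TRUE`).
#' @export
train_unsupervised <- function(cube, spikes, iterations = NULL) {
  stopifnot(inherits(cube, "snn_cube"), inherits(spikes, "spike_train_set"))
  if (length(cube$weight) == 0L) {
    abort("cube has no connections; call init_small_world() first.")
  }
  iterations <- iterations %||% cube$stdp$iterations
  for (it in seq_len(iterations)) {
    for (i in seq_len(dim(spikes)[1L])) {
      res <- run_cube(cube, sample_polarity(spikes, i), learn = TRUE)
      cube$weight <- res$weight
    }
  }
  cube$trained <- TRUE
  cube
}

#' Recall rasters for every sample
#'
#' Convenience wrapper: simulates each sample with learning off and returns
#' the list of rasters (reservoir states) used to train or query the
#' classifier.
#'
#' @inheritParams train_unsupervised
#' @return List of `spike_raster`, one per sample.
#' @export
recall_rasters <- function(cube, spikes) {
  lapply(seq_len(dim(spikes)[1L]), function(i) {
    simulate_cube(cube, spikes, i, learn = FALSE)
  })
}
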