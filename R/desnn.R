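#' deSNN classifier parameters
#'
#' Rank-order coding with spike-driven drift: the j-th reservoir neuron's
#' synapse onto an output neuron is initialized to `alpha * mod^order(j)`
#' where `order(j)` is the rank of j's first spike (earliest = 0), then
#' drifts up by `drift_up` at every later step where j spikes and down by
#' `drift_down` where it does not.  Recall compares weight vectors by
#' Euclidean distance (scaled by `sigma`) with a K-nearest-neighbour vote.
#'
#' @param mod Modulation factor in (0, 1) (default 0.8).
#' @param alpha Rank-order scale (default 1).
#' @param drift_up,drift_down Drift increments (default 0.005 each; may
#'   differ).
#' @param k_neighbors K for the nearest-neighbour vote (default 1).
#' @param sigma Distance scaling divisor (default 1).
#' @return A `desnn_params` list.
#' @export
desnn_params <- function(mod = 0.8, alpha = 1, drift_up = 0.005,
                         drift_down = 0.005, k_neighbors = 1L, sigma = 1) {
  if (!(mod > 0 && mod < 1)) abort("`mod` must lie in (0, 1).")
  if (!(alpha > 0)) abort("`alpha` must be positive.")
  if (drift_up < 0 || drift_down < 0) abort("drifts must be >= 0.")
  k_neighbors <- as.integer(k_neighbors)
  if (is.na(k_neighbors) || k_neighbors < 1L) abort("`k_neighbors` must be >= 1.")
  if (!(sigma > 0)) abort("`sigma` must be positive.")
  structure(list(mod = mod, alpha = alpha, drift_up = drift_up,
                 drift_down = drift_down, k_neighbors = k_neighbors,
                 sigma = sigma),
            class = "desnn_params")
}

#' Encode a reservoir state as an output-neuron weight vector
#'
#' First-spike ranks are taken over all neurons that fired (ties share
#' ascending ranks, broken by neuron index); silent neurons get weight 0 and
#' never drift.  After its first spike, a neuron's weight accumulates
#' `+drift_up` per spiking step and `-drift_down` per silent step.
#'
#' @param raster A `spike_raster`.
#' @param params [desnn_params()].
#' @return Numeric weight vector, one entry per reservoir neuron.
#' @export
#' @examples
#' r <- structure(list(fired = diag(3) > 0, first_spike_time = 1:3),
#'                class = "spike_raster")
#' encode_state(r, desnn_params(drift_up = 0, drift_down = 0))  # 1, 0.8, 0.64
encode_state <- function(raster, params = desnn_params()) {
  stopifnot(inherits(raster, "spike_raster"), inherits(params, "desnn_params"))
  fs <- raster$first_spike_time
  n <- length(fs)
  Tn <- ncol(raster$fired)
  w <- numeric(n)
  act <- which(!is.na(fs))
  if (!length(act)) return(w)
  ord <- act[order(fs[act], act)]          # earliest first, ties by index
  w[ord] <- params$alpha * params$mod^(seq_along(ord) - 1)
  n_fires <- rowSums(raster$fired[act, , drop = FALSE])
  steps_after <- Tn - fs[act]
  up <- n_fires - 1                         # spikes after the first one
  w[act] <- w[act] + params$drift_up * up -
    params$drift_down * (steps_after - up)
  w
}

#' Train the deSNN output layer
#'
#' One output neuron per training sample: its weight vector is the
#' rank-order + drift encoding of that sample's reservoir state, its class
#' the sample's label.
#'
#' @param rasters List of `spike_raster`, one per sample.
#' @param labels Class label per raster.
#' @param params [desnn_params()].
#' @return A `desnn_model`.
#' @export
desnn_train <- function(rasters, labels, params = desnn_params()) {
  if (length(rasters) == 0L) abort("no training rasters supplied.")
  if (length(labels) != length(rasters)) {
    abort("`labels` and `rasters` lengths differ.")
  }
  labels <- factor(labels)
  W <- do.call(rbind, lapply(rasters, encode_state, params = params))
  structure(
    list(weights = W, labels = labels, class_set = levels(labels),
         params = params),
    class = "desnn_model"
  )
}

#' @export
print.desnn_model <- function(x, ...) {
  cat(sprintf("<desnn_model> %d output neurons over %d reservoir neurons, classes: %s\n",
              nrow(x$weights), ncol(x$weights),
              paste(x$class_set, collapse = ", ")))
  invisible(x)
}

#' Classify a reservoir state
#'
#' Encodes the query raster with the model's parameters and votes over the K
#' nearest stored output neurons (Euclidean distance / `sigma`).  K > 1 ties
#' break by smallest summed distance, then by class order.
#'
#' @param model A `desnn_model`.
#' @param raster A `spike_raster` for the query sample.
#' @return A list: `class` (factor level), `neighbor_ids`, `distances`.
#' @export
desnn_classify <- function(model, raster) {
  stopifnot(inherits(model, "desnn_model"))
  if (is.null(model$weights) || nrow(model$weights) == 0L) {
    abort("model has no output neurons.")
  }
  wq <- encode_state(raster, model$params)
  if (length(wq) != ncol(model$weights)) {
    abort("query raster size does not match the model's reservoir.")
  }
  d <- sqrt(colSums((t(model$weights) - wq)^2)) / model$params$sigma
  k <- min(model$params$k_neighbors, length(d))
  nb <- order(d)[seq_len(k)]
  votes <- table(factor(model$labels[nb], levels = model$class_set))
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(d[nb][model$labels[nb] == cl]),
                   numeric(1L))
    top <- top[order(sums, match(top, model$class_set))][1L]
  }
  list(class = factor(top, levels = model$class_set),
       neighbor_ids = nb, distances = d[nb])
}

#' @export
tidy.desnn_model <- function(x, ...) {
  tibble(
    output_neuron = seq_len(nrow(x$weights)),
    class = x$labels,
    n_active = rowSums(x$weights != 0),
    weight_norm = sqrt(rowSums(x$weights^2))
  )
}

#' @export
glance.desnn_model <- function(x, ...) {
  tibble(
    n_output_neurons = nrow(x$weights),
    n_reservoir_neurons = ncol(x$weights),
    n_classes = length(x$class_set),
    mod = x$params$mod,
    k_neighbors = x$params$k_neighbors
  )
}
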