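#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spike raster
#'
#' @param object A `spike_raster`.
#' @param ... Unused.
#' @return A ggplot: time on x, neuron index on y, one point per spike.
#' @export
autoplot.spike_raster <- function(object, ...) {
  idx <- which(object$fired, arr.ind = TRUE)
  df <- tibble(neuron = idx[, 1L], time = idx[, 2L])
  ggplot(df, aes(x = .data$time, y = .data$neuron)) +
    geom_point(shape = "|", size = 2) +
    labs(x = "time step", y = "neuron") +
    theme_minimal()
}

#' Plot a sample set
#'
#' Faceted traces of a few samples per class, one line per variable.
#'
#' @param object A [sample_set()].
#' @param samples Sample indices to show (default: first sample of each
#'   class).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sample_set <- function(object, samples = NULL, ...) {
  samples <- samples %||%
    vapply(levels(object$labels),
           function(l) which(object$labels == l)[1L], integer(1L))
  df <- as_tibble(object) |>
    filter(.data$sample_id %in% samples) |>
    mutate(class = object$labels[.data$sample_id])
  ggplot(df, aes(x = .data$time_index, y = .data$value,
                 group = .data$variable, colour = .data$variable)) +
    geom_line(alpha = 0.7, show.legend = FALSE) +
    facet_wrap(~ sample_id + class, labeller = "label_both") +
    labs(x = "time index", y = "value") +
    theme_minimal()
}
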