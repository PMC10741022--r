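#' Two-class signal-to-noise-ratio variable ranking
#'
#' Ranks variables (channels/voxels) by their power to discriminate two
#' classes: each sample is aggregated to its time-mean per variable, and
#' `SNR = |mu1 - mu2| / (sd1 + sd2)` is computed over the class-wise
#' aggregates (population standard deviations).  Variables with SNR strictly
#' above `threshold` are selected, ordered by descending SNR.
#'
#' @param data A [sample_set()] with exactly two classes (>= 2 samples each).
#' @param threshold Selection threshold (default 0.4).
#' @param aggregate `"time_mean"` (default; SNR of per-sample time-means) or
#'   `"per_timepoint"` (mean over time of per-timepoint SNRs).
#' @param cap Finite stand-in for an infinite SNR (distinct means with zero
#'   spread).
#' @return A tibble (class `snr_ranking`) with columns `variable`, `snr`,
#'   `selected`, sorted by descending SNR.
#' @export
snr_rank <- function(data, threshold = 0.4,
                     aggregate = c("time_mean", "per_timepoint"),
                     cap = 1e6) {
  stopifnot(inherits(data, "sample_set"))
  aggregate <- match.arg(aggregate)
  labels <- data$labels
  if (nlevels(labels) != 2L) {
    abort("SNR ranking is defined for exactly 2 classes.")
  }
  if (any(tabulate(labels) < 2L)) {
    abort("each class needs at least 2 samples.")
  }
  g1 <- labels == levels(labels)[1L]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  snr_of <- function(a1, a2) {
    num <- abs(mean(a1) - mean(a2))
    den <- pop_sd(a1) + pop_sd(a2)
    if (den == 0) {
      if (num == 0) 0 else cap
    } else {
      min(num / den, cap)
    }
  }
  snr <- vapply(seq_len(n_variables(data)), function(v) {
    if (aggregate == "time_mean") {
      agg <- rowMeans(data$values[, v, , drop = TRUE])
      snr_of(agg[g1], agg[!g1])
    } else {
      mean(vapply(seq_len(n_time(data)), function(t) {
        x <- data$values[, v, t]
        snr_of(x[g1], x[!g1])
      }, numeric(1L)))
    }
  }, numeric(1L))
  out <- tibble(variable = data$variable_names, snr = snr,
                selected = snr > threshold) |>
    arrange(desc(.data$snr))
  attr(out, "threshold") <- threshold
  class(out) <- c("snr_ranking", class(out))
  out
}

#' Write an SNR ranking to CSV
#'
#' @param ranking An `snr_ranking` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_snr_ranking <- function(ranking, path) {
  readr::write_csv(ranking, path)
  invisible(path)
}

#' @export
autoplot.snr_ranking <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::mutate(object,
                      variable = factor(.data$variable,
                                        levels = rev(.data$variable)))
  ggplot(df, aes(x = .data$variable, y = .data$snr,
                 fill = .data$selected)) +
    geom_col() +
    geom_hline(yintercept = thr, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "signal-to-noise ratio", fill = "selected") +
    theme_minimal()
}

#' Evolved connectivity around the input neurons of trained reservoirs
#'
#' For each class-specific trained cube and each input variable, averages the
#' absolute weight of every connection whose two endpoints both lie within
#' `radius` of the variable's input neuron.  High local connectivity around
#' an input marks it as discriminative for that class (biomarker profiling).
#'
#' @param cubes Named list of trained `snn_cube` objects, one per class, each
#'   trained on that class's samples only.
#' @param radius Neighbourhood radius; defaults to each cube's small-world
#'   `max_distance` (or its lambda when no cutoff was used).
#' @return A tibble (class `connectivity_profile`) with columns `class`,
#'   `variable`, `mean_abs_weight`.
#' @export
connectivity_profile <- function(cubes, radius = NULL) {
  if (is.null(names(cubes)) || any(names(cubes) == "")) {
    abort("`cubes` must be a named list (one trained cube per class).")
  }
  rows <- imap(cubes, function(cube, cl) {
    stopifnot(inherits(cube, "snn_cube"))
    if (!isTRUE(cube$trained)) abort("all cubes must be trained.")
    if (is.null(cube$input_map)) abort("cube has no input map.")
    r <- radius %||% cube$sw$max_distance %||% cube$sw$lambda
    co <- cube$template$coordinates
    vals <- vapply(seq_along(cube$input_map), function(k) {
      centre <- co[cube$input_map[k], ]
      d2 <- colSums((t(co) - centre)^2)
      near <- d2 <= r^2
      sel <- near[cube$pre] & near[cube$post]
      if (any(sel)) mean(abs(cube$weight[sel])) else 0
    }, numeric(1L))
    tibble(class = cl, variable = names(cube$input_map),
           mean_abs_weight = vals)
  })
  out <- list_rbind(rows)
  class(out) <- c("connectivity_profile", class(out))
  out
}

#' Per-class mean of a connectivity profile
#'
#' Arithmetic mean of the per-variable connectivity values of each class (the
#' trailing "average" column of a profile table).
#'
#' @param profile A long table with columns `class` and a per-variable value
#'   column (`mean_abs_weight`, or `value` for tables read from CSV).
#' @return Tibble with columns `class`, `mean_abs_weight`.
#' @export
profile_class_means <- function(profile) {
  col <- intersect(c("mean_abs_weight", "value"), names(profile))[1L]
  if (is.na(col)) abort("no connectivity value column found.")
  profile |>
    group_by(.data$class) |>
    summarise(mean_abs_weight = mean(.data[[col]]), .groups = "drop")
}

#' Widen a connectivity profile into a report table
#'
#' One row per class, one column per input variable, plus a trailing
#' arithmetic `average` column.
#'
#' @param profile A `connectivity_profile`.
#' @return A wide tibble.
#' @export
connectivity_table <- function(profile) {
  wide <- tidyr::pivot_wider(profile, names_from = "variable",
                             values_from = "mean_abs_weight")
  wide$average <- profile_class_means(profile)$mean_abs_weight[
    match(wide$class, profile_class_means(profile)$class)]
  wide
}

#' Input-neuron spiking proportions
#'
#' Shares of the total input-neuron spiking activity carried by each input
#' variable across a set of rasters.  The lowest-ranked variable is the
#' natural first candidate for spatial masking at recall.
#'
#' @param rasters List of `spike_raster` objects from one trained cube.
#' @param input_map Named neuron index per variable (see [map_inputs()]).
#' @return Named numeric vector of proportions (sums to 1 when any input
#'   neuron spiked).
#' @export
spiking_proportion <- function(rasters, input_map) {
  counts <- vapply(input_map, function(j) {
    sum(vapply(rasters, function(r) sum(r$fired[j, ]), numeric(1L)))
  }, numeric(1L))
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}
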