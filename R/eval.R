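#' Retained Memory Accuracy
#'
#' Ratio of the accuracy retained under a partial-recall condition to the
#' full model's accuracy, `RMA = Ar / Af`.  Both arguments must be on the
#' same scale (both proportions or both percentages).
#'
#' @param retained Accuracy of the partial-recall condition (Ar).
#' @param full Accuracy of the full model (Af); must be positive.
#' @return `retained / full`.
#' @export
#' @examples
#' rma(95, 100)   # 0.95
#' rma(76, 80)    # 0.95
rma <- function(retained, full) {
  if (!is.numeric(retained) || !is.numeric(full)) {
    abort("`retained` and `full` must be numeric.")
  }
  if (any(full <= 0)) abort("RMA is undefined for full accuracy <= 0.")
  if (any(retained < 0)) abort("`retained` must be >= 0.")
  retained / full
}

#' Truncate the time axis of a sample set or spike train set
#'
#' Keeps the first `floor(fraction * T)` time points (at least 1), leaving
#' all variables untouched.  Truncating to an early prefix emulates recalling
#' a trained model before the full recording is available.
#'
#' @param x A [sample_set()] or `spike_train_set`.
#' @param fraction Fraction of the time axis to keep, in (0, 1].
#' @return Object of the same class with a shortened time axis.
#' @export
truncate_temporal <- function(x, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  UseMethod("truncate_temporal")
}

#' @export
truncate_temporal.sample_set <- function(x, fraction) {
  keep <- max(1L, floor(fraction * n_time(x)))
  sample_set(x$values[, , seq_len(keep), drop = FALSE], labels = x$labels,
             coordinates = x$coordinates, variable_names = x$variable_names)
}

#' @export
truncate_temporal.spike_train_set <- function(x, fraction) {
  keep <- max(1L, floor(fraction * dim(x)[3L]))
  x$polarity <- x$polarity[, , seq_len(keep), drop = FALSE]
  x$filtered <- x$filtered[, , seq_len(keep), drop = FALSE]
  x
}

#' Mask input variables of a spike train set
#'
#' Zeroes the spike trains of every variable not in `keep`, so the masked
#' variables inject nothing during recall.  The reservoir and its input map
#' are untouched — the model is never retrained, only queried with less
#' spatial information.
#'
#' @param spikes A `spike_train_set`.
#' @param keep Character vector of variable names to retain (non-empty subset
#'   of the set's variables).
#' @return The masked `spike_train_set` (same shape).
#' @export
mask_variables <- function(spikes, keep) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (length(keep) == 0L) abort("`keep` must name at least one variable.")
  unknown <- setdiff(keep, spikes$variable_names)
  if (length(unknown)) {
    abort(paste0("unknown variables: ", paste(unknown, collapse = ", ")))
  }
  drop <- setdiff(spikes$variable_names, keep)
  if (length(drop)) spikes$polarity[, drop, ] <- 0L
  attr(spikes, "masked_variables") <- drop
  spikes
}

#' A partial-recall condition
#'
#' @param time_fraction Fraction of the time axis used at recall, in (0, 1].
#' @param keep_variables Variables injected at recall (`NULL` = all).
#' @param split `"resubstitution"` (validate on the training samples;
#'   association accuracy) or `"holdout"` (validate on held-out samples;
#'   generalization accuracy).
#' @param split_seed Seed for the stratified holdout split.
#' @return A `recall_spec`.
#' @export
recall_spec <- function(time_fraction = 1, keep_variables = NULL,
                        split = c("resubstitution", "holdout"),
                        split_seed = NULL) {
  split <- match.arg(split)
  if (time_fraction <= 0 || time_fraction > 1) {
    abort("`time_fraction` must lie in (0, 1].")
  }
  structure(list(time_fraction = time_fraction,
                 keep_variables = keep_variables,
                 split = split, split_seed = split_seed),
            class = "recall_spec")
}

recall_mode <- function(spec, n_all_vars) {
  spatial <- !is.null(spec$keep_variables) &&
    length(spec$keep_variables) < n_all_vars
  paste0(if (spatial) "spatial_" else "temporal_",
         if (spec$split == "resubstitution") "association" else "generalization")
}

#' Fit the full spatio-temporal associative memory model
#'
#' Runs the whole training pipeline on complete data: spike-encode, build and
#' wire the reservoir, map the variables to input neurons, train the
#' reservoir weights with STDP, then train one deSNN output neuron per
#' sample on the recall rasters.
#'
#' @param data A [sample_set()] with all variables over the full time window.
#' @param config A [stam_config()]; its `seed` drives every random stage.
#' @param template Optional `neuron_template`; defaults to the grid described
#'   in `config$template`.
#' @return A `stam_fit` holding the trained cube, the deSNN model and the
#'   encoder settings.
#' @export
stam_fit <- function(data, config = stam_config(), template = NULL) {
  stopifnot(inherits(data, "sample_set"), inherits(config, "stam_config"))
  spikes <- step_forward_encode(data, config$encoder)
  template <- template %||% grid_template(config$template$nx,
                                          config$template$ny,
                                          config$template$nz,
                                          config$template$spacing)
  im <- map_inputs(template, data$coordinates,
                   rescale = config$template$rescale_inputs)
  sw <- config$small_world
  sw$seed <- sw$seed %||% stage_seed(config$seed, SEED_OFFSETS[["cube_init"]])
  cube <- new_snn_cube(template, lif = config$lif, stdp = config$stdp,
                       input_gain = config$input_gain, input_map = im)
  cube <- init_small_world(cube, sw)
  cube <- train_unsupervised(cube, spikes)
  rasters <- recall_rasters(cube, spikes)
  model <- desnn_train(rasters, data$labels, config$desnn)
  structure(
    list(cube = cube, model = model, encoder = config$encoder,
         config = config, variable_names = data$variable_names,
         n_train = n_samples(data), n_time = n_time(data)),
    class = "stam_fit"
  )
}

#' @export
print.stam_fit <- function(x, ...) {
  cat(sprintf("<stam_fit> %d training samples, %d variables x %d time steps\n",
              x$n_train, length(x$variable_names), x$n_time))
  print(x$cube)
  print(x$model)
  invisible(x)
}

#' @export
glance.stam_fit <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_variables = length(x$variable_names),
    n_time = x$n_time,
    n_neurons = x$cube$n_neurons,
    n_connections = length(x$cube$weight),
    mean_abs_weight = mean(abs(x$cube$weight))
  )
}

# Encode -> truncate -> mask -> recall -> classify every sample.
recall_predictions <- function(fit, data, spec) {
  spikes <- step_forward_encode(data, fit$encoder)
  if (spec$time_fraction < 1) {
    spikes <- truncate_temporal(spikes, spec$time_fraction)
  }
  if (!is.null(spec$keep_variables)) {
    spikes <- mask_variables(spikes, spec$keep_variables)
  }
  preds <- character(n_samples(data))
  for (i in seq_len(n_samples(data))) {
    raster <- simulate_cube(fit$cube, spikes, i, learn = FALSE)
    preds[i] <- as.character(desnn_classify(fit$model, raster)$class)
  }
  factor(preds, levels = levels(data$labels))
}

#' Evaluate a partial-recall condition
#'
#' Recalls the trained full model on (possibly) truncated time and masked
#' variables, with learning off throughout: neither the reservoir weights nor
#' the output neurons change.  Returns the condition's accuracy, the
#' full-model reference accuracy, and their ratio (RMA).
#'
#' @param fit A `stam_fit` trained on complete data.
#' @param data The [sample_set()] to recall on (the training data for
#'   association accuracy; held-out data for generalization accuracy).
#' @param spec A [recall_spec()].
#' @param full_accuracy Reference accuracy Af of the full condition
#'   `(time_fraction = 1, all variables)` on `data`; computed on the fly when
#'   `NULL`.
#' @return One-row tibble (class `stam_eval`): mode, time_fraction,
#'   n_variables, split, accuracy, full_accuracy, rma and a confusion-matrix
#'   list column.
#' @export
stam_evaluate <- function(fit, data, spec = recall_spec(),
                          full_accuracy = NULL) {
  stopifnot(inherits(fit, "stam_fit"), inherits(data, "sample_set"),
            inherits(spec, "recall_spec"))
  if (!is.null(spec$keep_variables)) {
    unknown <- setdiff(spec$keep_variables, fit$variable_names)
    if (length(unknown)) {
      abort(paste0("recall spec references unknown variables: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  preds <- recall_predictions(fit, data, spec)
  acc <- mean(preds == data$labels)
  if (is.null(full_accuracy)) {
    full_spec <- recall_spec(1, NULL, spec$split, spec$split_seed)
    identity_cond <- spec$time_fraction == 1 &&
      (is.null(spec$keep_variables) ||
         setequal(spec$keep_variables, fit$variable_names))
    full_accuracy <- if (identity_cond) acc else
      mean(recall_predictions(fit, data, full_spec) == data$labels)
  }
  out <- tibble(
    mode = recall_mode(spec, length(fit$variable_names)),
    time_fraction = spec$time_fraction,
    n_variables = length(spec$keep_variables %||% fit$variable_names),
    split = spec$split,
    accuracy = acc,
    full_accuracy = full_accuracy,
    rma = rma(acc, full_accuracy),
    confusion = list(table(truth = data$labels, predicted = preds))
  )
  class(out) <- c("stam_eval", class(out))
  out
}

# Stratified half split: index list train/test.
stratified_split <- function(labels, seed, train_fraction = 0.5) {
  if (is.null(seed)) abort("holdout evaluation requires a `split_seed`.")
  withr::with_seed(as.integer(seed), {
    idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      sample(ix, floor(length(ix) * train_fraction))
    }), use.names = FALSE)
  })
  list(train = sort(idx), test = setdiff(seq_along(labels), idx))
}

subset_samples <- function(data, idx) {
  sample_set(data$values[idx, , , drop = FALSE], labels = data$labels[idx],
             coordinates = data$coordinates,
             variable_names = data$variable_names)
}

#' Sweep partial-recall conditions into a report table
#'
#' Cartesian sweep over time fractions, variable subsets and split modes.
#' For resubstitution ("100/100") the model is fitted and validated on all
#' samples; for holdout ("50/50") it is fitted on a seeded stratified half
#' and validated on the other half.  Each condition's RMA is taken relative
#' to the full-recall accuracy under the *same* split mode.
#'
#' @param data A [sample_set()].
#' @param config A [stam_config()].
#' @param fractions Numeric vector of time fractions in (0, 1].
#' @param variable_subsets List of variable-name vectors (`NULL` entry = all
#'   variables).
#' @param splits Character vector from `c("resubstitution", "holdout")`.
#' @param split_seed Seed of the stratified holdout split (defaults to a seed
#'   derived from `config$seed`).
#' @param template Optional `neuron_template` passed to [stam_fit()].
#' @return A tibble (class `stam_suite`) with one row per condition.
#' @export
run_stam_suite <- function(data, config = stam_config(),
                           fractions = c(1, 0.95, 0.9, 0.8),
                           variable_subsets = list(NULL),
                           splits = "resubstitution",
                           split_seed = NULL, template = NULL) {
  stopifnot(inherits(data, "sample_set"))
  splits <- match.arg(splits, c("resubstitution", "holdout"),
                      several.ok = TRUE)
  split_seed <- split_seed %||% stage_seed(config$seed, SEED_OFFSETS[["split"]])
  rows <- list()
  for (sp in splits) {
    if (sp == "holdout") {
      ix <- stratified_split(data$labels, split_seed)
      fit <- stam_fit(subset_samples(data, ix$train), config, template)
      eval_data <- subset_samples(data, ix$test)
    } else {
      fit <- stam_fit(data, config, template)
      eval_data <- data
    }
    full <- stam_evaluate(fit, eval_data,
                          recall_spec(1, NULL, sp, split_seed))
    af <- full$accuracy
    for (keep in variable_subsets) {
      for (fr in fractions) {
        spec <- recall_spec(fr, keep, sp, split_seed)
        is_full <- fr == 1 && (is.null(keep) ||
                                 setequal(keep, data$variable_names))
        rows[[length(rows) + 1L]] <- if (is_full) full else
          stam_evaluate(fit, eval_data, spec, full_accuracy = af)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stam_suite", setdiff(class(out), "stam_eval"))
  out
}

#' Write a recall-sweep report
#'
#' Writes the flat columns to CSV and a JSON twin that also carries the
#' per-condition confusion matrices.
#'
#' @param suite A `stam_suite` tibble from [run_stam_suite()].
#' @param path CSV path; the JSON twin replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(suite, path) {
  flat <- dplyr::select(suite, -"confusion")
  readr::write_csv(flat, path)
  js <- purrr::map(seq_len(nrow(suite)), function(i) {
    c(as.list(flat[i, ]),
      list(confusion = as.data.frame(suite$confusion[[i]])))
  })
  jsonlite::write_json(js, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
autoplot.stam_suite <- function(object, ...) {
  ggplot(object,
         aes(x = .data$time_fraction, y = .data$rma,
             colour = .data$mode, group = .data$mode)) +
    geom_line() +
    geom_point(aes(size = .data$accuracy), alpha = 0.8) +
    scale_x_reverse(labels = function(x) paste0(100 * x, "%")) +
    labs(x = "time window used at recall", y = "retained memory accuracy",
         colour = "recall mode", size = "accuracy") +
    theme_minimal()
}
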