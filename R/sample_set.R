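#' Labelled spatio-temporal sample sets
#'
#' A `sample_set` bundles a `samples x variables x time` numeric array with a
#' class label per sample and a 3D coordinate per variable (electrode or voxel
#' position).  It is the common input container for spike encoding, reservoir
#' training and recall evaluation.
#'
#' @param values Numeric array with dimensions `samples x variables x time`.
#' @param labels Class label per sample (coerced to factor). Length must equal
#'   `dim(values)[1]`.
#' @param coordinates Numeric matrix `variables x 3` of (x, y, z) positions.
#' @param variable_names Optional character vector of variable (channel/voxel)
#'   names; defaults to `V1..Vk` or the dimnames of `values`.
#'
#' @return An object of class `sample_set`.
#' @export
#' @examples
#' x <- sample_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)),
#'                 labels = c("a", "b"),
#'                 coordinates = matrix(rnorm(9), 3, 3))
#' dim(x)
sample_set <- function(values, labels, coordinates, variable_names = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-dimensional array (samples x variables x time).")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and non-missing.")
  }
  d <- dim(values)
  if (length(labels) != d[1L]) {
    abort(sprintf("`labels` has length %d but there are %d samples.",
                  length(labels), d[1L]))
  }
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != d[2L] || ncol(coordinates) != 3L) {
    abort("`coordinates` must be a (variables x 3) matrix.")
  }
  storage.mode(coordinates) <- "double"
  variable_names <- variable_names %||% dimnames(values)[[2L]] %||%
    paste0("V", seq_len(d[2L]))
  if (length(variable_names) != d[2L] || anyDuplicated(variable_names)) {
    abort("`variable_names` must uniquely name every variable.")
  }
  dimnames(values) <- list(NULL, variable_names, NULL)
  rownames(coordinates) <- variable_names
  colnames(coordinates) <- c("x", "y", "z")
  structure(
    list(values = values, labels = factor(labels),
         coordinates = coordinates, variable_names = variable_names),
    class = "sample_set"
  )
}

#' @export
dim.sample_set <- function(x) dim(x$values)

#' Number of samples, variables and time points
#'
#' @param x A [sample_set()] or [spike_train_set].
#' @return Integer count.
#' @export
n_samples <- function(x) dim(x)[1L]

#' @rdname n_samples
#' @export
n_variables <- function(x) dim(x)[2L]

#' @rdname n_samples
#' @export
n_time <- function(x) dim(x)[3L]

#' @export
print.sample_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sample_set> %d samples x %d variables x %d time points\n",
              d[1L], d[2L], d[3L]))
  cat("  classes:",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.sample_set <- function(x, ...) {
  d <- dim(x)
  tibble(
    sample_id  = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    variable   = rep(rep(x$variable_names, each = d[1L]), times = d[3L]),
    time_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value      = as.vector(x$values)
  ) |>
    arrange(.data$sample_id, .data$variable, .data$time_index)
}

#' Read and write sample sets as plain CSV
#'
#' The on-disk dialect is a long-format values file with columns
#' `sample_id, variable, time_index, value`, plus two sidecar files next to it:
#' `<stem>_labels.csv` (`sample_id, label`) and `<stem>_coordinates.csv`
#' (`variable, x, y, z`).
#'
#' @param x A [sample_set()].
#' @param path Path of the long-format values CSV; sidecar paths are derived
#'   from it.
#' @return `write_sample_set()` returns `path` invisibly; `read_sample_set()`
#'   returns a [sample_set()].
#' @export
write_sample_set <- function(x, path) {
  stopifnot(inherits(x, "sample_set"))
  readr::write_csv(as_tibble(x), path)
  stem <- sub("\\.csv$", "", path)
  readr::write_csv(
    tibble(sample_id = seq_len(n_samples(x)), label = as.character(x$labels)),
    paste0(stem, "_labels.csv")
  )
  co <- x$coordinates
  readr::write_csv(
    tibble(variable = x$variable_names,
           x = co[, 1L], y = co[, 2L], z = co[, 3L]),
    paste0(stem, "_coordinates.csv")
  )
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  vals <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "variable", "time_index", "value")
  if (!all(need %in% names(vals))) {
    abort(paste0("values CSV must have columns ", paste(need, collapse = ", ")))
  }
  stem <- sub("\\.csv$", "", path)
  labs <- readr::read_csv(paste0(stem, "_labels.csv"), show_col_types = FALSE)
  coords <- readr::read_csv(paste0(stem, "_coordinates.csv"),
                            show_col_types = FALSE)
  vars <- unique(vals$variable)
  s <- sort(unique(vals$sample_id))
  t <- sort(unique(vals$time_index))
  a <- array(NA_real_, c(length(s), length(vars), length(t)),
             dimnames = list(NULL, vars, NULL))
  a[cbind(match(vals$sample_id, s), match(vals$variable, vars),
          match(vals$time_index, t))] <- vals$value
  cm <- as.matrix(coords[match(vars, coords$variable), c("x", "y", "z")])
  sample_set(a, labels = labs$label[match(s, labs$sample_id)],
             coordinates = cm, variable_names = vars)
}
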