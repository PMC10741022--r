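#' Neuron coordinate templates
#'
#' A `neuron_template` positions reservoir neurons in 3D space.  Real brain
#' templates (Talairach/MNI coordinate lists) can be loaded from CSV with
#' [load_template()]; [grid_template()] builds a regular synthetic lattice as
#' a stand-in when no atlas is available.
#'
#' @param coordinates Numeric `n x 3` matrix of distinct (x, y, z) positions.
#' @param region_label Optional character vector of per-neuron region names.
#' @return A `neuron_template`.
#' @export
neuron_template <- function(coordinates, region_label = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L || nrow(coordinates) < 1L) {
    abort("`coordinates` must be an (n x 3) matrix with n >= 1.")
  }
  storage.mode(coordinates) <- "double"
  if (anyNA(coordinates)) abort("template coordinates must be numeric.")
  if (anyDuplicated(coordinates) > 0L) {
    abort("two neurons share identical coordinates.")
  }
  colnames(coordinates) <- c("x", "y", "z")
  if (!is.null(region_label) && length(region_label) != nrow(coordinates)) {
    abort("`region_label` must have one entry per neuron.")
  }
  structure(list(coordinates = coordinates, region_label = region_label),
            class = "neuron_template")
}

#' @export
print.neuron_template <- function(x, ...) {
  cat(sprintf("<neuron_template> %d neurons\n", nrow(x$coordinates)))
  invisible(x)
}

#' Regular 3D lattice template
#'
#' @param nx,ny,nz Lattice dimensions (each >= 1).
#' @param spacing Lattice constant (distance between neighbouring neurons).
#' @return A `neuron_template` with `nx * ny * nz` neurons centered at the
#'   origin.
#' @export
#' @examples
#' grid_template(2, 2, 2)  # 8 neurons, nearest-neighbour distance 1
grid_template <- function(nx, ny, nz, spacing = 1) {
  dims <- c(nx, ny, nz)
  if (any(is.na(dims)) || any(dims < 1)) {
    abort("all lattice dimensions must be >= 1.")
  }
  axis <- function(n) (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = axis(nx), y = axis(ny), z = axis(nz))
  neuron_template(as.matrix(g))
}

#' Load / save a neuron template CSV
#'
#' The CSV must have columns `x, y, z` and optionally `label`; row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param template A `neuron_template` to write.
#' @return `load_template()` returns a `neuron_template`;
#'   `write_template()` returns `path` invisibly.
#' @export
load_template <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort("template CSV must have columns x, y, z.")
  }
  if (!all(vapply(df[c("x", "y", "z")], is.numeric, logical(1L)))) {
    abort("template coordinates must be numeric.")
  }
  neuron_template(as.matrix(df[, c("x", "y", "z")]),
                  region_label = if ("label" %in% names(df)) df$label)
}

#' @rdname load_template
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "neuron_template"))
  df <- as_tibble(template$coordinates)
  if (!is.null(template$region_label)) df$label <- template$region_label
  readr::write_csv(df, path)
  invisible(path)
}

#' Map input variables to their nearest template neurons
#'
#' Each variable is assigned the closest template neuron (Euclidean distance).
#' Variables are processed in order; when a neuron is already taken, the next
#' nearest unused neuron is assigned, so the mapping is injective.
#'
#' @param template A `neuron_template`.
#' @param variable_coords Numeric `k x 3` matrix of variable positions
#'   (electrode/voxel coordinates), optionally row-named.
#' @param rescale If `TRUE`, the variable coordinates' bounding box is first
#'   rescaled onto the template's bounding box so electrode layouts spread
#'   over the whole reservoir; `FALSE` (default) maps raw coordinates.
#' @return Named integer vector: neuron index per variable.
#' @export
map_inputs <- function(template, variable_coords, rescale = FALSE) {
  stopifnot(inherits(template, "neuron_template"))
  vc <- as.matrix(variable_coords)
  if (ncol(vc) != 3L) abort("`variable_coords` must be (k x 3).")
  tc <- template$coordinates
  if (nrow(vc) > nrow(tc)) {
    abort("more input variables than template neurons.")
  }
  if (rescale) {
    for (j in 1:3) {
      r <- range(vc[, j])
      tr <- range(tc[, j])
      vc[, j] <- if (diff(r) == 0) mean(tr) else
        tr[1L] + (vc[, j] - r[1L]) / diff(r) * diff(tr)
    }
  }
  used <- logical(nrow(tc))
  idx <- integer(nrow(vc))
  for (v in seq_len(nrow(vc))) {
    d2 <- colSums((t(tc) - vc[v, ])^2)
    ord <- order(d2)            # stable: ties resolve to lower neuron index
    pick <- ord[!used[ord]][1L]
    idx[v] <- pick
    used[pick] <- TRUE
  }
  names(idx) <- rownames(variable_coords) %||% paste0("V", seq_len(nrow(vc)))
  idx
}
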