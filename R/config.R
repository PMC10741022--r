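#' Full pipeline configuration
#'
#' Bundles every stage's parameters.  The defaults reproduce the reference
#' EEG configuration: step-forward threshold 0.5 with window-5 smoothing,
#' leak 0.002, STDP rate 0.01, firing threshold 0.5, one training pass,
#' refractory 6, no long-distance connections, mod 0.8, drift 0.005, K = 1,
#' sigma = 1.  One global `seed` fans out to per-stage seeds (wiring, splits)
#' via a fixed rule, so a configured run is reproducible end to end.
#'
#' @param seed Global integer seed.
#' @param encoder [encoder_params()].
#' @param lif [lif_params()].
#' @param stdp [stdp_params()].
#' @param small_world [small_world_params()]; its `seed` defaults to one
#'   derived from the global seed at fit time.
#' @param desnn [desnn_params()].
#' @param template Reservoir lattice description: list with `nx, ny, nz,
#'   spacing, rescale_inputs` (default 11 x 11 x 11 grid — the closest cube
#'   to a 1471-neuron anatomical template — with input coordinates rescaled
#'   onto the lattice).
#' @param input_gain Current injected per input spike.
#' @return A `stam_config`.
#' @export
stam_config <- function(seed = 1L, encoder = encoder_params(),
                        lif = lif_params(), stdp = stdp_params(),
                        small_world = small_world_params(),
                        desnn = desnn_params(),
                        template = list(nx = 11L, ny = 11L, nz = 11L,
                                        spacing = 1, rescale_inputs = TRUE),
                        input_gain = 1) {
  stopifnot(inherits(encoder, "encoder_params"), inherits(lif, "lif_params"),
            inherits(stdp, "stdp_params"),
            inherits(small_world, "small_world_params"),
            inherits(desnn, "desnn_params"))
  tpl_defaults <- list(nx = 11L, ny = 11L, nz = 11L, spacing = 1,
                       rescale_inputs = TRUE)
  bad <- setdiff(names(template), names(tpl_defaults))
  if (length(bad)) abort(paste0("unknown template keys: ",
                                paste(bad, collapse = ", ")))
  template <- modifyList(tpl_defaults, template)
  structure(list(seed = as.integer(seed), encoder = encoder, lif = lif,
                 stdp = stdp, small_world = small_world, desnn = desnn,
                 template = template, input_gain = input_gain),
            class = "stam_config")
}

#' @export
print.stam_config <- function(x, ...) {
  cat(sprintf(
    paste0("<stam_config> seed %d | theta %g, window %d | grid %dx%dx%d | ",
           "leak %g, thr %g, refractory %d | STDP %g x%d | mod %g, K %d\n"),
    x$seed, x$encoder$spike_threshold, x$encoder$window_size,
    x$template$nx, x$template$ny, x$template$nz,
    x$lif$leak_rate, x$lif$firing_threshold, x$lif$refractory_time,
    x$stdp$a_plus, x$stdp$iterations, x$desnn$mod, x$desnn$k_neighbors))
  invisible(x)
}

# plain nested list for serialization (classes stripped, NULLs dropped)
config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) purrr::compact(lapply(unclass(x), strip)) else x
  }
  strip(unclass(config))
}

#' Save / load a configuration (YAML or JSON)
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).  An
#' empty file loads as the full default configuration; unknown keys are an
#' error; omitted keys take their defaults.  `save(load(x))` is idempotent.
#'
#' @param config A [stam_config()].
#' @param path File path.
#' @return `save_config()` returns `path` invisibly; `load_config()` a
#'   `stam_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "stam_config"))
  lst <- config_to_list(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    abort("config path must end in .yaml, .yml or .json.")
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config path must end in .yaml, .yml or .json.")
  }
  raw <- raw %||% list()
  if (!is.list(raw)) abort("config file does not contain a mapping.")
  defaults <- config_to_list(stam_config())
  check_keys <- function(x, ref, prefix = "") {
    bad <- setdiff(names(x), names(ref))
    if (length(bad)) {
      abort(paste0("unknown config keys: ", prefix,
                   paste(bad, collapse = paste0(", ", prefix))))
    }
    for (k in names(x)) {
      if (is.list(x[[k]]) && is.list(ref[[k]])) {
        check_keys(x[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  # sub-lists with open-ended defaults (seed/max_distance may be absent)
  full_ref <- defaults
  full_ref$small_world$seed <- NA
  full_ref$small_world$max_distance <- full_ref$small_world$max_distance %||% 3
  check_keys(raw, full_ref)
  merged <- modifyList(defaults, raw)
  stam_config(
    seed = merged$seed,
    encoder = do.call(encoder_params, merged$encoder),
    lif = do.call(lif_params, merged$lif),
    stdp = do.call(stdp_params, merged$stdp),
    small_world = do.call(small_world_params, merged$small_world),
    desnn = do.call(desnn_params, merged$desnn),
    template = merged$template,
    input_gain = merged$input_gain
  )
}
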