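#' Persist and restore a fitted model
#'
#' Writes a `stam_fit` as plain text files in a directory: connection
#' triplets, neuron coordinates, the input map and the deSNN weight matrix as
#' CSV, plus one JSON file with every parameter set.  Everything needed to
#' recall the model is preserved.
#'
#' @param fit A `stam_fit`.
#' @param dir Output directory (created if needed).
#' @return `write_stam_fit()` returns `dir` invisibly; `read_stam_fit()`
#'   returns the restored `stam_fit`.
#' @export
write_stam_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "stam_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  cube <- fit$cube
  readr::write_csv(tibble(pre = cube$pre, post = cube$post,
                          weight = cube$weight, sign = cube$sign),
                   p("connections.csv"))
  write_template(cube$template, p("template.csv"))
  readr::write_csv(tibble(variable = names(cube$input_map),
                          neuron = as.integer(cube$input_map)),
                   p("input_map.csv"))
  W <- as.data.frame(fit$model$weights)
  names(W) <- paste0("n", seq_along(W))
  W$label <- as.character(fit$model$labels)
  readr::write_csv(W, p("output_weights.csv"))
  meta <- list(
    config = config_to_list(fit$config),
    small_world_seed = cube$sw$seed,
    variable_names = fit$variable_names,
    n_train = fit$n_train, n_time = fit$n_time,
    n_neurons = cube$n_neurons, input_gain = cube$input_gain
  )
  jsonlite::write_json(meta, p("model.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @rdname write_stam_fit
#' @export
read_stam_fit <- function(dir) {
  p <- function(f) file.path(dir, f)
  meta <- jsonlite::read_json(p("model.json"), simplifyVector = TRUE)
  cfg_list <- meta$config
  config <- stam_config(
    seed = cfg_list$seed,
    encoder = do.call(encoder_params, cfg_list$encoder),
    lif = do.call(lif_params, cfg_list$lif),
    stdp = do.call(stdp_params, cfg_list$stdp),
    small_world = do.call(small_world_params, cfg_list$small_world),
    desnn = do.call(desnn_params, cfg_list$desnn),
    template = cfg_list$template,
    input_gain = cfg_list$input_gain
  )
  template <- load_template(p("template.csv"))
  im_df <- readr::read_csv(p("input_map.csv"), show_col_types = FALSE)
  im <- setNames(as.integer(im_df$neuron), im_df$variable)
  cube <- new_snn_cube(template, lif = config$lif, stdp = config$stdp,
                       input_gain = meta$input_gain, input_map = im)
  conns <- readr::read_csv(p("connections.csv"), show_col_types = FALSE)
  n <- cube$n_neurons
  cube$pre <- as.integer(conns$pre)
  cube$post <- as.integer(conns$post)
  cube$weight <- conns$weight
  cube$sign <- as.integer(conns$sign)
  m <- nrow(conns)
  cube$in_conn <- split(seq_len(m), factor(cube$post, levels = seq_len(n)))
  cube$out_conn <- split(seq_len(m), factor(cube$pre, levels = seq_len(n)))
  sw <- config$small_world
  sw$seed <- meta$small_world_seed
  cube$sw <- sw
  cube$trained <- TRUE
  Wdf <- readr::read_csv(p("output_weights.csv"), show_col_types = FALSE)
  labels <- factor(Wdf$label)
  W <- as.matrix(Wdf[, setdiff(names(Wdf), "label")])
  dimnames(W) <- NULL
  model <- structure(list(weights = W, labels = labels,
                          class_set = levels(labels),
                          params = config$desnn),
                     class = "desnn_model")
  structure(
    list(cube = cube, model = model, encoder = config$encoder,
         config = config, variable_names = meta$variable_names,
         n_train = meta$n_train, n_time = meta$n_time),
    class = "stam_fit"
  )
}
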