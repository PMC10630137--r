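#' Checkpoint files for trained objects
#'
#' Trained potentials, transport maps, and autoencoders serialize to a
#' single HDF5 file: one dataset per named parameter array (doubles stored
#' bit-exactly) plus a JSON metadata block holding the configuration.
#' `read_checkpoint()` restores the object; round trips are bit-exact.
#'
#' @param object An `icnn`, `transport_map`, or `autoencoder`.
#' @param path Destination file (conventionally `.h5`).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns the restored object.
#' @export
write_checkpoint <- function(object, path) {
  UseMethod("write_checkpoint")
}

ckpt_open <- function(path, kind, meta) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(kind, path, "kind")
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)),
                 path, "meta_json")
}

ckpt_write_arrays <- function(path, group, arrays) {
  rhdf5::h5createGroup(path, group)
  for (nm in names(arrays))
    rhdf5::h5write(arrays[[nm]], path, paste0(group, "/", nm))
}

ckpt_read_arrays <- function(path, group) {
  contents <- rhdf5::h5ls(path)
  nms <- contents$name[contents$group == paste0("/", group)]
  out <- lapply(nms, function(nm) rhdf5::h5read(path, paste0(group, "/", nm)))
  names(out) <- nms
  out
}

#' @export
write_checkpoint.icnn <- function(object, path) {
  ckpt_open(path, "icnn",
            list(input_dim = object$input_dim, widths = object$widths,
                 activation = object$activation, slope = object$slope,
                 seed = object$seed))
  ckpt_write_arrays(path, "params", icnn_param_list(object))
  rhdf5::h5closeAll()
  invisible(path)
}

#' @export
write_checkpoint.transport_map <- function(object, path) {
  ckpt_open(path, "transport_map",
            list(input_dim = object$input_dim,
                 feature_names = object$feature_names,
                 config = unclass(object$config),
                 selected_iteration = object$selected_iteration,
                 g = list(activation = object$g$activation,
                          slope = object$g$slope, seed = object$g$seed,
                          widths = object$g$widths),
                 f = list(activation = object$f$activation,
                          slope = object$f$slope, seed = object$f$seed,
                          widths = object$f$widths)))
  ckpt_write_arrays(path, "g", icnn_param_list(object$g))
  ckpt_write_arrays(path, "f", icnn_param_list(object$f))
  ckpt_write_arrays(path, "log", list(
    iteration = object$log$iteration, loss_f = object$log$loss_f,
    loss_g = object$log$loss_g, penalty = object$log$penalty))
  rhdf5::h5closeAll()
  invisible(path)
}

#' @export
write_checkpoint.autoencoder <- function(object, path) {
  L <- length(object$weights$W)
  arrays <- c(stats::setNames(object$weights$W, paste0("W", seq_len(L))),
              stats::setNames(object$weights$b, paste0("b", seq_len(L))))
  ckpt_open(path, "autoencoder",
            list(config = unclass(object$config),
                 feature_names = object$feature_names,
                 input_dim = object$input_dim,
                 train_error = object$train_error,
                 val_error = object$val_error, n_layers = L))
  ckpt_write_arrays(path, "params", arrays)
  rhdf5::h5closeAll()
  invisible(path)
}

rebuild_icnn <- function(meta, params) {
  net <- icnn_init(meta$input_dim %||% length(params$Wx1),
                   utils::head(meta$widths, -1L),
                   meta$activation, meta$slope, meta$seed %||% 0L)
  icnn_set_params(net, params)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  kind <- as.character(rhdf5::h5read(path, "kind"))
  meta <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta_json")))
  out <- switch(
    kind,
    icnn = {
      params <- ckpt_read_arrays(path, "params")
      rebuild_icnn(meta, params)
    },
    transport_map = {
      cfg <- meta$config
      cfg$hidden_widths <- as.integer(cfg$hidden_widths)
      config <- do.call(ot_train_config, cfg)
      gm <- c(meta$g, list(input_dim = meta$input_dim))
      fm <- c(meta$f, list(input_dim = meta$input_dim))
      log <- ckpt_read_arrays(path, "log")
      structure(
        list(g = rebuild_icnn(gm, ckpt_read_arrays(path, "g")),
             f = rebuild_icnn(fm, ckpt_read_arrays(path, "f")),
             input_dim = meta$input_dim,
             feature_names = meta$feature_names,
             config = config,
             log = tibble::tibble(iteration = as.integer(log$iteration),
                                  loss_f = as.numeric(log$loss_f),
                                  loss_g = as.numeric(log$loss_g),
                                  penalty = as.numeric(log$penalty)),
             selected_iteration = meta$selected_iteration,
             eval_mmd = NULL),
        class = "transport_map")
    },
    autoencoder = {
      cfg <- meta$config
      cfg$hidden_widths <- as.integer(cfg$hidden_widths)
      config <- do.call(ae_config, cfg)
      params <- ckpt_read_arrays(path, "params")
      L <- meta$n_layers
      structure(
        list(weights = list(
               W = lapply(seq_len(L), function(i) params[[paste0("W", i)]]),
               b = lapply(seq_len(L), function(i) as.numeric(params[[paste0("b", i)]]))),
             config = config, feature_names = meta$feature_names,
             input_dim = meta$input_dim, train_error = meta$train_error,
             val_error = meta$val_error),
        class = "autoencoder")
    },
    stop(sprintf("unknown checkpoint kind `%s`", kind), call. = FALSE))
  rhdf5::h5closeAll()
  out
}
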