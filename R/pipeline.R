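#' Default pipeline configuration
#'
#' The full configuration tree consumed by [run_pipeline()], with every
#' default filled in: data source, annotation keys, split protocol, model
#' architecture (including the optional autoencoder latent pathway),
#' training hyperparameters (batch 256, learning rate 1e-4, Adam betas
#' (0.5, 0.9), penalty weight 1, ten inner updates, four hidden layers of
#' width 64, 50-dimensional latent space), and evaluation settings (50
#' marker features, 50 MMD length scales).
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  list(
    data = list(
      path = NULL, format = "auto", kind = "matrix",   # matrix | fourI | scrna
      target_sum = 1e4, min_genes = 200, min_cells = 3, n_hvg = 1000,
      simulate = list(kind = "gaussian_shift",          # or mixture
                      n_source = 2000, n_target = 2000, d = 2,
                      shift = c(3, 0), mixture_shift = 3, noise_sd = 1)),
    condition_key = "condition", sample_key = NULL, cell_type_key = NULL,
    control_label = "control", perturbation = "perturbed",
    split = list(mode = "iid", holdout = NULL, test_size = 500,
                 eval_size = 500),
    model = list(use_ae = FALSE, latent_dim = 50, ae_hidden = c(128),
                 ae_epochs = 50, ae_lr = 1e-3,
                 hidden_widths = c(64, 64, 64, 64),
                 activation = "softplus", slope = 0.2),
    training = list(batch_size = 256, lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                    lambda = 1, inner_g_steps = 10, n_iter = 10000,
                    warmstart_steps = 1000, warmstart_f = TRUE,
                    checkpoint_every = 500,
                    select_by_eval_mmd = FALSE, log_every = 100),
    evaluation = list(feature_mode = "all", n_markers = 50, n_gammas = 50),
    seed = 0)
}

usage_error <- function(msg) {
  structure(class = c("usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(usage_error(sprintf("unknown configuration key `%s`", full)))
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv))
        stop(usage_error(sprintf("key `%s` expects a section", full)))
      defaults[[key]] <- merge_config(dv, uv, c(path, key))
    } else {
      defaults[[key]] <- coerce_config_value(dv, uv, full)
    }
  }
  defaults
}

coerce_config_value <- function(default, value, key) {
  if (is.null(value)) return(NULL)
  if (is.null(default)) return(value)
  if (is.numeric(default)) {
    out <- suppressWarnings(as.numeric(value))
    if (anyNA(out))
      stop(usage_error(sprintf("key `%s` expects a number, got `%s`",
                               key, paste(value, collapse = ","))))
    return(out)
  }
  if (is.logical(default)) {
    v <- toupper(as.character(value))
    if (is.logical(value)) return(value)
    if (all(v %in% c("TRUE", "FALSE", "T", "F", "YES", "NO", "1", "0")))
      return(v %in% c("TRUE", "T", "YES", "1"))
    stop(usage_error(sprintf("key `%s` expects a logical, got `%s`",
                             key, paste(value, collapse = ","))))
  }
  as.character(value)
}

#' Parse a pipeline configuration
#'
#' Reads a YAML configuration file (missing or empty files give all
#' defaults), validates every key against [default_run_config()], and
#' applies `key.path=value` overrides last. Unknown keys and type
#' mismatches raise usage errors.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Character vector of `section.key=value` assignments.
#' @param seed Optional seed overriding `seed` in the file.
#' @return The resolved configuration list.
#' @export
parse_run_config <- function(path = NULL, overrides = character(),
                             seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(usage_error(sprintf("config file not found: %s", path)))
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  for (ov in overrides) {
    eq <- regexpr("=", ov, fixed = TRUE)
    if (eq < 0)
      stop(usage_error(sprintf("override `%s` is not of the form key=value", ov)))
    key <- substr(ov, 1, eq - 1)
    val <- substr(ov, eq + 1, nchar(ov))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (p in utils::head(parts, -1)) {
      if (!p %in% names(node))
        stop(usage_error(sprintf("unknown configuration key `%s`", key)))
      node <- node[[p]]
    }
    leaf <- utils::tail(parts, 1)
    if (!leaf %in% names(node))
      stop(usage_error(sprintf("unknown configuration key `%s`", key)))
    new_val <- coerce_config_value(node[[leaf]],
                                   strsplit(val, ",", fixed = TRUE)[[1]], key)
    cfg[[parts]] <- new_val
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

cfg_ot_config <- function(cfg) {
  tr <- cfg$training
  md <- cfg$model
  ot_train_config(
    batch_size = tr$batch_size, lr = tr$lr, beta1 = tr$beta1,
    beta2 = tr$beta2, lambda = tr$lambda, inner_g_steps = tr$inner_g_steps,
    n_iter = tr$n_iter, hidden_widths = md$hidden_widths,
    activation = md$activation, slope = md$slope,
    warmstart_steps = tr$warmstart_steps,
    warmstart_f = tr$warmstart_f,
    checkpoint_every = tr$checkpoint_every,
    select_by_eval_mmd = tr$select_by_eval_mmd,
    log_every = tr$log_every, seed = cfg$seed)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

write_manifest <- function(outdir, task, cfg) {
  jsonlite::write_json(
    list(task = task, seed = cfg$seed, config = cfg,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(outdir, paste0("manifest_", task, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Orchestrates the end-to-end workflow on disk: `simulate` writes a
#' synthetic control/perturbed dataset; `preprocess` applies the configured
#' normalization; `train-ae` fits the latent-space autoencoder;
#' `train` splits the data, fits the transport map (optionally in the
#' latent space), and writes a checkpoint; `predict` pushes the held-out
#' test control cells through the map; `evaluate` scores predictions
#' against the observed perturbed test cells alongside the identity and
#' observed baselines. Every stage writes a manifest (resolved
#' configuration and seed) next to its artifacts, so a run can be
#' reproduced from its output directory alone.
#'
#' @param task One of `"simulate"`, `"preprocess"`, `"train-ae"`,
#'   `"train"`, `"predict"`, `"evaluate"`.
#' @param outdir Output directory (created if needed). Stages that consume
#'   earlier artifacts look for them here.
#' @param config A resolved configuration list from [parse_run_config()],
#'   or a path to a YAML file.
#' @param input Optional input data file (defaults to the `data.path`
#'   configuration entry, or to the `simulate` stage's output in `outdir`).
#' @param seed Optional seed override.
#' @param format On-disk population format (`"csv"`, `"tsv"`, or `"h5ad"`)
#'   for artifacts written by this run.
#' @param overrides Character vector of `key=value` configuration
#'   overrides.
#' @param quiet Suppress progress messages.
#' @return The stage's primary artifact paths, invisibly (a named list).
#' @export
run_pipeline <- function(task = c("simulate", "preprocess", "train-ae",
                                  "train", "predict", "evaluate"),
                         outdir, config = NULL, input = NULL, seed = NULL,
                         format = "csv", overrides = character(),
                         quiet = FALSE) {
  task <- match.arg(task)
  cfg <- if (is.list(config)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    config
  } else parse_run_config(config, overrides, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "h5ad") "h5ad" else format
  data_file <- function() {
    f <- input %||% cfg$data$path %||%
      first_existing(file.path(outdir, paste0("data.", c("csv", "tsv", "h5ad"))))
    if (is.null(f) || !file.exists(f))
      stop(sprintf("no input data found (looked for `%s`)",
                   f %||% file.path(outdir, "data.*")), call. = FALSE)
    f
  }
  read_pop_cfg <- function(f) {
    read_population(f, format = "auto", condition_key = cfg$condition_key,
                    sample_key = cfg$sample_key,
                    cell_type_key = cfg$cell_type_key)
  }
  artifacts <- switch(
    task,
    simulate = {
      sim <- cfg$data$simulate
      d <- as.integer(sim$d)
      pair <- if (identical(sim$kind, "mixture")) {
        s <- sim$mixture_shift
        sh1 <- c(s, rep(0, d - 1)); sh2 <- c(-s, rep(0, d - 1))
        mu1 <- c(-2, rep(0, d - 1)); mu2 <- c(2, rep(0, d - 1))
        sample_mixture_pair(mixture_spec(
          c(0.5, 0.5), list(mu1, mu2),
          list(diag(sim$noise_sd^2, d), diag(sim$noise_sd^2, d)),
          shifts = list(sh1, sh2), n_source = sim$n_source,
          n_target = sim$n_target, seed = cfg$seed))
      } else {
        shift <- rep_len(as.numeric(sim$shift), d)
        sample_gaussian_pair(gaussian_spec(
          rep(0, d), diag(sim$noise_sd^2, d), shift, diag(sim$noise_sd^2, d),
          n_source = sim$n_source, n_target = sim$n_target, seed = cfg$seed))
      }
      pop <- dplyr::bind_rows(pair$source, pair$target)
      pop$cell_id <- paste0("cell_", seq_len(nrow(pop)))
      class(pop) <- c("cell_pop", class(tibble::tibble()))
      out <- file.path(outdir, paste0("data.", ext))
      write_population(pop, out, format = format,
                       condition_key = cfg$condition_key,
                       cell_type_key = cfg$cell_type_key)
      pipeline_log(quiet, "simulated %d cells (%s) -> %s", nrow(pop),
                   sim$kind, out)
      list(data = out)
    },
    preprocess = {
      pop <- read_pop_cfg(data_file())
      pop <- switch(cfg$data$kind,
        fourI = normalize_4i(pop, cfg$control_label),
        scrna = {
          p <- normalize_scrna(pop, cfg$data$target_sum, cfg$data$min_genes,
                               cfg$data$min_cells)
          n_hvg <- min(cfg$data$n_hvg, length(pop_feature_names(p)))
          idx <- select_hvg(p, n_hvg)
          p[c(intersect(pop_reserved, names(p)), names(idx))]
        },
        matrix = pop)
      class(pop) <- c("cell_pop", class(tibble::tibble()))
      out <- file.path(outdir, paste0("processed.", ext))
      write_population(pop, out, format = format,
                       condition_key = cfg$condition_key,
                       sample_key = cfg$sample_key,
                       cell_type_key = cfg$cell_type_key)
      pipeline_log(quiet, "preprocessed (%s) -> %s", cfg$data$kind, out)
      list(processed = out)
    },
    `train-ae` = {
      pop <- read_pop_cfg(data_file())
      md <- cfg$model
      fit <- fit_autoencoder(pop, ae_config(
        latent_dim = md$latent_dim, hidden_widths = md$ae_hidden,
        epochs = md$ae_epochs, lr = md$ae_lr, seed = cfg$seed))
      out <- file.path(outdir, "ae.h5")
      write_checkpoint(fit, out)
      pipeline_log(quiet, "autoencoder val mse %.4g -> %s", fit$val_error, out)
      list(ae = out)
    },
    train = {
      pop <- read_pop_cfg(data_file())
      splits <- make_splits(pop, split_spec(
        cfg$split$mode, cfg$split$holdout, cfg$split$test_size,
        cfg$split$eval_size, seed = cfg$seed))
      readr::write_csv(splits, file.path(outdir, "splits.csv"),
                       progress = FALSE)
      train_rows <- splits$row[splits$split == "train"]
      src <- pop[intersect(train_rows, which(pop$condition == cfg$control_label)), ]
      tgt <- pop[intersect(train_rows, which(pop$condition == cfg$perturbation)), ]
      if (nrow(src) == 0 || nrow(tgt) == 0)
        stop(sprintf("no training cells for `%s` vs `%s`",
                     cfg$control_label, cfg$perturbation), call. = FALSE)
      ae <- NULL
      if (cfg$model$use_ae) {
        ae_path <- file.path(outdir, "ae.h5")
        if (!file.exists(ae_path))
          run_pipeline("train-ae", outdir, cfg, input = data_file(),
                       format = format, quiet = quiet)
        ae <- read_checkpoint(ae_path)
        src <- encode(ae, src)
        tgt <- encode(ae, tgt)
      }
      map <- fit_transport_map(src, tgt, cfg_ot_config(cfg))
      out <- file.path(outdir, "map.h5")
      write_checkpoint(map, out)
      readr::write_csv(map$log, file.path(outdir, "training_log.csv"),
                       progress = FALSE)
      pipeline_log(quiet, "trained %d outer iterations -> %s",
                   map$config$n_iter, out)
      list(map = out, splits = file.path(outdir, "splits.csv"))
    },
    predict = {
      pop <- read_pop_cfg(data_file())
      splits <- readr::read_csv(file.path(outdir, "splits.csv"),
                                show_col_types = FALSE, progress = FALSE)
      map <- read_checkpoint(file.path(outdir, "map.h5"))
      test_rows <- splits$row[splits$split == "test"]
      ctl <- pop[intersect(test_rows, which(pop$condition == cfg$control_label)), ]
      if (cfg$model$use_ae) {
        ae <- read_checkpoint(file.path(outdir, "ae.h5"))
        pred <- decode(ae, transport(map, encode(ae, ctl)))
      } else {
        pred <- transport(map, ctl)
      }
      pred$condition <- paste0("predicted_", cfg$perturbation)
      class(pred) <- c("cell_pop", class(tibble::tibble()))
      out <- file.path(outdir, paste0("predictions.", ext))
      write_population(pred, out, format = format,
                       condition_key = cfg$condition_key,
                       cell_type_key = cfg$cell_type_key)
      pipeline_log(quiet, "predicted %d cells -> %s", nrow(pred), out)
      list(predictions = out)
    },
    evaluate = {
      pop <- read_pop_cfg(data_file())
      splits <- readr::read_csv(file.path(outdir, "splits.csv"),
                                show_col_types = FALSE, progress = FALSE)
      pred <- read_population(
        first_existing(file.path(outdir, paste0("predictions.", c("csv", "tsv", "h5ad")))),
        condition_key = cfg$condition_key)
      test_rows <- splits$row[splits$split == "test"]
      eval_rows <- splits$row[splits$split == "eval"]
      obs <- pop[intersect(test_rows, which(pop$condition == cfg$perturbation)), ]
      ctl <- pop[intersect(test_rows, which(pop$condition == cfg$control_label)), ]
      obs_eval <- pop[intersect(eval_rows, which(pop$condition == cfg$perturbation)), ]
      ev <- cfg$evaluation
      gammas <- mmd_default_gammas(ev$n_gammas)
      reports <- list(
        model = evaluate_prediction(pred, obs, ctl, ev$feature_mode,
                                    ev$n_markers, gammas, "model"),
        identity = evaluate_prediction(baseline_identity(ctl), obs, ctl,
                                       ev$feature_mode, ev$n_markers, gammas,
                                       "identity"),
        observed = evaluate_prediction(baseline_observed(obs_eval, obs), obs,
                                       ctl, ev$feature_mode, ev$n_markers,
                                       gammas, "observed"))
      tidy_all <- dplyr::bind_rows(lapply(reports, tidy))
      readr::write_csv(tidy_all, file.path(outdir, "evaluation.csv"),
                       progress = FALSE)
      jsonlite::write_json(
        lapply(reports, function(r)
          list(baseline = r$baseline_tag, mmd_mean = r$mmd_mean,
               l2_means = r$l2_means, r2_means = r$r2_means,
               n_pred = r$n_pred, n_obs = r$n_obs)),
        file.path(outdir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      pipeline_log(quiet,
                   "evaluation: model mmd %.4g | identity %.4g | observed %.4g",
                   reports$model$mmd_mean, reports$identity$mmd_mean,
                   reports$observed$mmd_mean)
      list(evaluation = file.path(outdir, "evaluation.json"),
           table = file.path(outdir, "evaluation.csv"))
    })
  write_manifest(outdir, task, cfg)
  invisible(artifacts)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1]] else NULL
}
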