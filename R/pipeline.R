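default_run_config <- function() {
  list(
    seed = 1L,
    mode = "mechanistic",
    cohort = list(),        # overrides for cohort_spec()
    emg = list(),           # overrides for emg_filter_settings()
    mtg = list(),           # overrides for mtg_params()
    arm = list(hand_load_mass = 0.5),  # overrides for arm_model()
    narx = list(n_l = 1L, n_n = 20L, n_u = 3L, n_y = 5L),
    train = list(),         # overrides for train_settings()
    grid = list(),          # overrides for grid_spec()
    selection = list(use_recurrent = FALSE),
    split = c(14L, 2L, 1L)
  )
}

apply_overrides <- function(fn, overrides, ...) {
  known <- names(formals(fn))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0L)
    imnet_stop(paste0("unknown configuration key(s): ",
                      paste(unknown, collapse = ", ")), "imnet_config_error")
  do.call(fn, c(overrides, list(...)))
}

#' Read a run configuration file
#'
#' A single YAML (or JSON) file configures every stage; unknown keys are
#' rejected. Top-level sections: `seed`, `mode`, `cohort`, `emg`, `mtg`,
#' `arm`, `narx`, `train`, `grid`, `selection`, `split` - each section
#' holds overrides for the corresponding constructor's defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or NULL for the
#'   built-in defaults.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      imnet_stop(paste0("config file not found: ", path), "imnet_io_error")
    user <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
    else {
      if (!requireNamespace("yaml", quietly = TRUE))
        imnet_stop("the yaml package is needed for YAML configs",
                   "imnet_config_error")
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L)
      imnet_stop(paste0("unknown configuration section(s): ",
                        paste(unknown, collapse = ", ")), "imnet_config_error")
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
        utils::modifyList(cfg[[k]], user[[k]])
      else user[[k]]
    }
  }
  structure(cfg, class = "run_config")
}

write_manifest <- function(dir, entries) {
  path <- file.path(dir, "manifest.json")
  entries$package_version <- as.character(utils::packageVersion("imnet"))
  entries$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[imnet:%s] %s", stage, sprintf(...)))
}

subject_dirs <- function(dir) {
  sort(list.dirs(dir, recursive = FALSE))
}

narx_from_config <- function(cfg, n_inputs, n_outputs) {
  apply_overrides(narx_config, cfg$narx, n_inputs = n_inputs,
                  n_outputs = n_outputs)
}

stage_synth <- function(cfg, out_dir) {
  spec <- apply_overrides(cohort_spec, cfg$cohort, seed = cfg$seed)
  cohort <- generate_cohort(spec, mode = cfg$mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anthro <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    anthro[[s$id]] <- as.list(s$anthropometrics)
    for (k in seq_along(s$trials)) {
      tdir <- file.path(out_dir, s$id, sprintf("trial%02d", k))
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      tr <- s$trials[[k]]
      write_timeseries(tr$inputs, file.path(tdir, "inputs.csv"))
      write_timeseries(tr$targets, file.path(tdir, "truth.csv"))
      raw_emg <- cohort$truth[[i]]$trials[[k]]$raw_emg
      if (!is.null(raw_emg))
        write_timeseries(raw_emg, file.path(tdir, "emg_raw.csv"))
    }
  }
  write_manifest(out_dir, list(command = "synth", seed = cfg$seed,
                               mode = cfg$mode,
                               spec = unclass(spec),
                               anthropometrics = anthro))
  pipeline_log("synth", "wrote %d subjects to %s", spec$n_subjects, out_dir)
  invisible(out_dir)
}

# read a prepared cohort directory into a list of subject datasets
read_cohort_dir <- function(dir, inputs_file = "inputs.csv",
                            targets_file = "envelopes.csv") {
  sdirs <- subject_dirs(dir)
  if (length(sdirs) == 0L)
    imnet_stop(paste0("no subject directories under ", dir), "imnet_io_error")
  lapply(sdirs, function(sd) {
    tdirs <- sort(list.dirs(sd, recursive = FALSE))
    trials <- lapply(tdirs, function(td) {
      tf <- file.path(td, targets_file)
      if (!file.exists(tf)) tf <- file.path(td, "truth.csv")
      list(inputs = read_timeseries(file.path(td, inputs_file)),
           targets = read_timeseries(tf))
    })
    list(id = basename(sd), trials = trials)
  })
}

stage_prep <- function(cfg, data_dir) {
  emg_set <- apply_overrides(emg_filter_settings, cfg$emg)
  sdirs <- subject_dirs(data_dir)
  n_done <- 0L
  for (sd in sdirs) {
    for (td in sort(list.dirs(sd, recursive = FALSE))) {
      raw_path <- file.path(td, "emg_raw.csv")
      if (file.exists(raw_path)) {
        env <- filter_emg_chain(read_timeseries(raw_path), emg_set)
        write_timeseries(env, file.path(td, "envelopes.csv"))
      } else if (file.exists(file.path(td, "truth.csv"))) {
        file.copy(file.path(td, "truth.csv"), file.path(td, "envelopes.csv"),
                  overwrite = TRUE)
      } else {
        imnet_stop(paste0("no EMG source in ", td), "imnet_io_error")
      }
      n_done <- n_done + 1L
    }
  }
  if (n_done == 0L)
    imnet_stop(paste0("no trial directories found under ", data_dir),
               "imnet_io_error")
  pipeline_log("prep", "prepared %d trials", n_done)
  invisible(data_dir)
}

stage_train <- function(cfg, data_dir, out_dir) {
  cohort <- read_cohort_dir(data_dir)
  split <- subject_split(cohort, cfg$split[1L], cfg$split[2L], cfg$split[3L],
                         seed = cfg$seed)
  tr1 <- cohort[[1]]$trials[[1]]
  ncfg <- narx_from_config(cfg, n_channels(tr1$inputs),
                           n_channels(tr1$targets))
  settings <- apply_overrides(train_settings, cfg$train, seed = cfg$seed)
  model <- init_model(ncfg, cfg$seed)
  fit <- lm_train(model, subject_trials(split$train),
                  subject_trials(split$val), subject_trials(split$test),
                  settings)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_narx(fit$model, file.path(out_dir, "model.json"))
  write_history(fit, file.path(out_dir, "history.csv"))
  write_manifest(out_dir, list(command = "train", seed = cfg$seed,
                               narx = unclass(ncfg),
                               split_subjects = split$indices,
                               best_epoch = fit$best_epoch,
                               stop_reason = fit$stop_reason))
  pipeline_log("train", "stopped (%s) at best epoch %d", fit$stop_reason,
               fit$best_epoch)
  invisible(out_dir)
}

stage_predict <- function(cfg, data_dir, model_path, out_dir) {
  model <- load_narx(model_path)
  cohort <- read_cohort_dir(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    for (k in seq_along(s$trials)) {
      tr <- s$trials[[k]]
      pred <- forward_closed_loop(model, tr$inputs$values)
      w <- narx_warmup(model$config)
      out <- mcts(pred, tr$inputs$rate_hz,
                  s$trials[[k]]$targets$channels,
                  tr$inputs$start_s + w / tr$inputs$rate_hz)
      tdir <- file.path(out_dir, s$id, sprintf("trial%02d", k))
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      write_timeseries(out, file.path(tdir, "predictions.csv"))
    }
  }
  write_manifest(out_dir, list(command = "predict", seed = cfg$seed,
                               model = model_path, data = data_dir))
  pipeline_log("predict", "wrote closed-loop predictions for %d subjects",
               length(cohort))
  invisible(out_dir)
}

stage_evaluate <- function(cfg, data_dir, model_path, out_dir) {
  model <- load_narx(model_path)
  cohort <- read_cohort_dir(data_dir)
  w <- narx_warmup(model$config)
  rows <- list()
  for (s in cohort) {
    for (k in seq_along(s$trials)) {
      tr <- s$trials[[k]]
      pred_ol <- forward_open_loop(model, tr$inputs$values, tr$targets$values)
      pred_cl <- forward_closed_loop(model, tr$inputs$values)
      y <- tr$targets$values[(w + 1L):n_samples(tr$targets), , drop = FALSE]
      safe_R <- function(a, b)
        tryCatch(regression_R(a, b), imnet_error = function(e) NA_real_)
      for (j in seq_len(ncol(y))) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s$id, trial = k, channel = colnames(y)[j],
          open_loop_R = safe_R(y[, j], pred_ol[, j]),
          closed_loop_R = safe_R(y[, j], pred_cl[, j]),
          open_loop_mse = mse(y[, j, drop = FALSE],
                              pred_ol[, j, drop = FALSE]),
          closed_loop_mse = mse(y[, j, drop = FALSE],
                                pred_cl[, j, drop = FALSE]))
      }
    }
  }
  metrics <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(command = "evaluate", seed = cfg$seed,
                               model = model_path, data = data_dir))
  pipeline_log("evaluate", "mean open-loop R = %.1f%%, closed-loop R = %.1f%%",
               mean(metrics$open_loop_R, na.rm = TRUE),
               mean(metrics$closed_loop_R, na.rm = TRUE))
  invisible(metrics)
}

stage_gridsearch <- function(cfg, data_dir, out_dir) {
  cohort <- read_cohort_dir(data_dir)
  spec <- apply_overrides(grid_spec, cfg$grid)
  settings <- apply_overrides(train_settings, cfg$train, seed = cfg$seed)
  res <- grid_search(spec, cohort, settings, split_sizes = cfg$split,
                     seed = cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res, file.path(out_dir, "grid_search.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(command = "gridsearch", seed = cfg$seed,
                               grid = unclass(spec)))
  invisible(res)
}

stage_sensitivity <- function(cfg, data_dir, out_dir) {
  cohort <- read_cohort_dir(data_dir)
  tr1 <- cohort[[1]]$trials[[1]]
  ncfg <- narx_from_config(cfg, n_channels(tr1$inputs),
                           n_channels(tr1$targets))
  settings <- apply_overrides(train_settings, cfg$train, seed = cfg$seed)
  rep <- backward_selection(cohort, ncfg,
                            use_recurrent = isTRUE(cfg$selection$use_recurrent),
                            settings = settings, seed = cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$phases, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  writeLines(rev(rep$dominance), file.path(out_dir, "dominance.txt"))
  write_manifest(out_dir, list(command = "sensitivity", seed = cfg$seed,
                               dominance = rep$dominance))
  invisible(rep)
}

#' Run a pipeline stage
#'
#' Ties the package stages into the end-to-end preparation/training
#' pipeline. `synth` writes a synthetic cohort directory (per subject and
#' trial: `inputs.csv`, `truth.csv`, and raw `emg_raw.csv` in mechanistic
#' mode). `prep` converts raw EMG to `envelopes.csv` targets. `train` fits
#' a NARX model on a subject split and saves the model archive plus
#' training history. `predict` runs the saved model closed-loop from the
#' biomechanical inputs alone (zero initial feedback). `evaluate` reports
#' per-channel open- and closed-loop R and MSE. `gridsearch` and
#' `sensitivity` wrap the corresponding model-selection procedures. Every
#' artifact directory receives a manifest with the settings, seed, and
#' package version.
#'
#' @param config a `run_config` (see [read_run_config]).
#' @param command one of `synth`, `prep`, `train`, `predict`, `evaluate`,
#'   `gridsearch`, `sensitivity`.
#' @param data_dir cohort directory (input for every command except
#'   `synth`, output for `synth`/`prep`).
#' @param out_dir artifact output directory.
#' @param model_path model archive for `predict`/`evaluate` (defaults to
#'   `out_dir/model.json` from a previous `train`).
#' @return stage-dependent artifact, invisibly.
#' @export
run_pipeline <- function(config, command, data_dir, out_dir = data_dir,
                         model_path = file.path(out_dir, "model.json")) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command, c("synth", "prep", "train", "predict",
                                  "evaluate", "gridsearch", "sensitivity"))
  switch(command,
         synth = stage_synth(config, data_dir),
         prep = stage_prep(config, data_dir),
         train = stage_train(config, data_dir, out_dir),
         predict = stage_predict(config, data_dir, model_path,
                                 file.path(out_dir, "predictions")),
         evaluate = stage_evaluate(config, data_dir, model_path, out_dir),
         gridsearch = stage_gridsearch(config, data_dir, out_dir),
         sensitivity = stage_sensitivity(config, data_dir, out_dir))
}
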