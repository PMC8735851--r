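#' Configuration grid specification
#'
#' Default ranges match the configuration search this model family is tuned
#' over: input taps 1-10, feedback taps 1-10, 1-3 hidden layers, 10-50
#' nodes in steps of 5 (a flat Cartesian product; multi-layer entries share
#' one node count across layers).
#'
#' @param n_u,n_y,n_l,n_n integer vectors of candidate values.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(n_u = 1:10, n_y = 1:10, n_l = 1:3,
                      n_n = seq(10L, 50L, by = 5L)) {
  if (any(lengths(list(n_u, n_y, n_l, n_n)) == 0L))
    imnet_stop("grid ranges must be non-empty", "imnet_parameter_error")
  structure(list(n_u = as.integer(n_u), n_y = as.integer(n_y),
                 n_l = as.integer(n_l), n_n = as.integer(n_n)),
            class = "grid_spec")
}

#' Enumerate all configurations of a grid
#'
#' @param spec a [grid_spec].
#' @param n_inputs,n_outputs channel counts shared by every configuration.
#' @return list of [narx_config] objects (flat Cartesian product).
#' @export
enumerate_grid <- function(spec, n_inputs = 5L, n_outputs = 6L) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- expand.grid(n_u = spec$n_u, n_y = spec$n_y, n_l = spec$n_l,
                   n_n = spec$n_n, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    narx_config(n_inputs, n_outputs, n_l = g$n_l[i], n_n = g$n_n[i],
                n_u = g$n_u[i], n_y = g$n_y[i]))
}

fit_and_score <- function(cfg, split, settings, seed) {
  model <- init_model(cfg, seed)
  tr <- subject_trials(split$train)
  va <- subject_trials(split$val)
  te <- subject_trials(split$test)
  fit <- lm_train(model, tr, va, te, settings)
  score <- function(trials) {
    pr <- lapply(trials, function(t)
      forward_open_loop(fit$model, as_trials(list(t))[[1]]$inputs,
                        as_trials(list(t))[[1]]$targets))
    w <- narx_warmup(cfg)
    tg <- lapply(trials, function(t) {
      y <- as_trials(list(t))[[1]]$targets
      y[(w + 1L):nrow(y), , drop = FALSE]
    })
    regression_R(do.call(rbind, tg), do.call(rbind, pr))
  }
  all_trials <- c(tr, va, te)
  list(fit = fit, train_R = score(tr), val_R = score(va), test_R = score(te),
       all_R = score(all_trials))
}

#' Configuration grid search
#'
#' Trains every configuration of the grid on a fixed subject split and
#' records the regression R on the training, validation, test, and pooled
#' data. The result ranks configurations by all-data R descending, breaking
#' ties by fewer parameters, then by enumeration order. The per-config
#' training budget is expressed in epochs. Individual configuration
#' failures are recorded (R = NA) and do not abort the search.
#'
#' @param spec a [grid_spec].
#' @param cohort list of subject datasets.
#' @param settings a [train_settings]; its `max_epochs` is overridden by
#'   `budget_epochs`.
#' @param budget_epochs per-configuration epoch cap.
#' @param split_sizes subject counts (train, val, test).
#' @param seed controls the split and every weight initialization.
#' @return a `grid_search_result`: data frame with one row per
#'   configuration (n_l, n_n, n_u, n_y, parameter_count, train/val/test/all
#'   R, rank), sorted by rank.
#' @export
grid_search <- function(spec, cohort, settings = train_settings(),
                        budget_epochs = 30L, split_sizes = c(14L, 2L, 1L),
                        seed = 1L) {
  configs <- if (inherits(spec, "grid_spec"))
    enumerate_grid(spec,
                   n_inputs = ncol(as_trials(list(cohort[[1]]$trials[[1]]))[[1]]$inputs),
                   n_outputs = ncol(as_trials(list(cohort[[1]]$trials[[1]]))[[1]]$targets))
  else spec
  split <- subject_split(cohort, split_sizes[1L], split_sizes[2L],
                         split_sizes[3L], seed = seed)
  settings$max_epochs <- as.integer(budget_epochs)
  settings$patience_epochs <- min(settings$patience_epochs,
                                  settings$max_epochs)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- tryCatch(fit_and_score(cfg, split, settings,
                                  seed = derive_seed(seed, i)),
                    error = function(e) NULL)
    data.frame(index = i, n_l = cfg$n_l, n_n = cfg$n_n, n_u = cfg$n_u,
               n_y = cfg$n_y, parameter_count = count_parameters(cfg),
               train_R = if (is.null(res)) NA_real_ else res$train_R,
               val_R = if (is.null(res)) NA_real_ else res$val_R,
               test_R = if (is.null(res)) NA_real_ else res$test_R,
               all_R = if (is.null(res)) NA_real_ else res$all_R)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$all_R, tab$parameter_count, tab$index, na.last = TRUE)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("grid_search_result", "data.frame"))
}

#' Subject-wise k-fold cross-validation
#'
#' Partitions subjects into k folds; each fold serves once as the
#' validation set while all remaining subjects train the model. With k equal
#' to the number of subjects this is leave-one-subject-out. Fold validation
#' R is recorded, with the average, maximum and minimum as summary.
#'
#' @param cohort list of subject datasets.
#' @param config a [narx_config].
#' @param k number of folds (<= number of subjects).
#' @param settings a [train_settings].
#' @param seed controls fold assignment and initializations.
#' @return list with `fold_R` (numeric vector), `average`, `max`, `min`,
#'   and `folds` (list of subject index vectors).
#' @export
kfold_cv <- function(cohort, config, k = length(cohort),
                     settings = train_settings(), seed = 1L) {
  n <- length(cohort)
  if (k > n) imnet_stop("k exceeds the number of subjects", "imnet_data_error")
  perm <- with_seed(seed, sample.int(n))
  folds <- split(perm, rep_len(seq_len(k), n))
  fold_R <- vapply(seq_len(k), function(i) {
    val_idx <- folds[[i]]
    tr <- subject_trials(cohort[-val_idx])
    va <- subject_trials(cohort[val_idx])
    model <- init_model(config, derive_seed(seed, i, 1L))
    fit <- lm_train(model, tr, va, settings = settings)
    preds <- lapply(as_trials(va), function(t)
      forward_open_loop(fit$model, t$inputs, t$targets))
    w <- narx_warmup(config)
    tg <- lapply(as_trials(va), function(t)
      t$targets[(w + 1L):nrow(t$targets), , drop = FALSE])
    regression_R(do.call(rbind, tg), do.call(rbind, preds))
  }, numeric(1))
  list(fold_R = fold_R, average = mean(fold_R), max = max(fold_R),
       min = min(fold_R), folds = folds)
}

general_model_R <- function(trials, cfg, settings, seed) {
  # general-model evaluation: all data trains, R measured on the same pool;
  # a degenerate fit (e.g. constant predictions) scores -Inf rather than
  # aborting a selection loop
  tryCatch({
    model <- init_model(cfg, seed)
    fit <- lm_train(model, trials, trials, settings = settings)
    preds <- lapply(trials, function(t)
      forward_open_loop(fit$model, t$inputs, t$targets))
    w <- narx_warmup(cfg)
    tg <- lapply(trials, function(t)
      t$targets[(w + 1L):nrow(t$targets), , drop = FALSE])
    regression_R(do.call(rbind, tg), do.call(rbind, preds))
  }, imnet_error = function(e) -Inf)
}

#' Per-channel estimability ranking
#'
#' Trains one single-output model per target channel on the pooled cohort
#' (the general model) and ranks channels by regression R descending -
#' identifying which muscle envelopes the biomechanical inputs can actually
#' estimate.
#'
#' @param cohort list of subject datasets with named target channels.
#' @param config a [narx_config] template (its `n_outputs` is set to 1).
#' @param settings a [train_settings].
#' @param top_m optionally select the best m channels.
#' @param seed RNG seed.
#' @return data frame (channel, R) sorted by R descending; if `top_m` is
#'   given, an attribute `selected` holds the top-m channel names.
#' @export
per_channel_evaluation <- function(cohort, config,
                                   settings = train_settings(),
                                   top_m = NULL, seed = 1L) {
  trials <- lapply(subject_trials(cohort), function(t) as_trials(list(t))[[1]])
  ch <- colnames(trials[[1]]$targets)
  if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(trials[[1]]$targets)))
  Rs <- vapply(seq_along(ch), function(j) {
    cfg1 <- narx_config(config$n_inputs, 1L, config$n_l, config$n_n,
                        config$n_u, config$n_y, config$hidden_activation,
                        config$output_range)
    tr1 <- lapply(trials, function(t)
      list(inputs = t$inputs, targets = t$targets[, j, drop = FALSE]))
    general_model_R(tr1, cfg1, settings, derive_seed(seed, j, 2L))
  }, numeric(1))
  out <- data.frame(channel = ch, R = Rs)
  out <- out[order(-out$R), ]
  rownames(out) <- NULL
  if (!is.null(top_m)) attr(out, "selected") <- out$channel[seq_len(top_m)]
  out
}

#' Sequential backward input selection
#'
#' Sensitivity analysis of the input channels. Phase 1 records the
#' performance of the full input set. Each subsequent phase trains one
#' model per remaining input with that input removed; the input whose
#' removal yields the highest regression R is the least dominant and is
#' eliminated. Phases repeat until a single input remains. The dominance
#' ranking is the elimination order reversed (last eliminated = most
#' dominant). In ANN mode the models are feedforward with taps (1, 0) -
#' the direct input-output relation, with the same layer/node counts; in
#' RNN mode the full delay configuration is used.
#'
#' @param cohort list of subject datasets (pooled general-model data).
#' @param config a [narx_config] template.
#' @param use_recurrent FALSE (default) for the ANN mode, TRUE for RNN.
#' @param settings a [train_settings].
#' @param seed RNG seed.
#' @return a `sensitivity_report`: list with `phases` (data frame: phase,
#'   removed_candidate, active inputs, R), `elimination_order`,
#'   `dominance` (most dominant first), `baseline_R`.
#' @export
backward_selection <- function(cohort, config, use_recurrent = FALSE,
                               settings = train_settings(), seed = 1L) {
  trials <- lapply(subject_trials(cohort), function(t) as_trials(list(t))[[1]])
  inames <- colnames(trials[[1]]$inputs)
  if (is.null(inames)) inames <- paste0("in", seq_len(ncol(trials[[1]]$inputs)))
  if (length(inames) < 2L)
    imnet_stop("backward selection needs at least 2 inputs", "imnet_data_error")
  n_out <- ncol(trials[[1]]$targets)
  make_cfg <- function(n_in) {
    if (use_recurrent)
      narx_config(n_in, n_out, config$n_l, config$n_n, config$n_u,
                  config$n_y, config$hidden_activation, config$output_range)
    else
      narx_config(n_in, n_out, config$n_l, config$n_n, n_u = 1L, n_y = 0L,
                  hidden_activation = config$hidden_activation,
                  output_range = config$output_range)
  }
  eval_subset <- function(active, seed_i) {
    cfg <- make_cfg(length(active))
    tr <- lapply(trials, function(t)
      list(inputs = t$inputs[, active, drop = FALSE], targets = t$targets))
    general_model_R(tr, cfg, settings, seed_i)
  }
  active <- inames
  phase_rows <- list()
  elim <- character(0)
  baseline <- eval_subset(active, derive_seed(seed, 0L, 3L))
  phase_rows[[1]] <- data.frame(phase = 1L, removed_candidate = NA_character_,
                                active = paste(active, collapse = "+"),
                                R = baseline)
  phase <- 1L
  while (length(active) > 1L) {
    phase <- phase + 1L
    cand_R <- vapply(seq_along(active), function(i)
      eval_subset(active[-i], derive_seed(seed, 100L * phase + i, 3L)),
      numeric(1))
    rows <- data.frame(phase = phase, removed_candidate = active,
                       active = vapply(seq_along(active), function(i)
                         paste(active[-i], collapse = "+"), character(1)),
                       R = cand_R)
    phase_rows[[phase]] <- rows
    # least dominant: removal yields highest R; ties by first occurrence
    drop_i <- which.max(cand_R)
    elim <- c(elim, active[drop_i])
    active <- active[-drop_i]
  }
  elim <- c(elim, active)  # the survivor is the most dominant
  structure(list(phases = do.call(rbind, phase_rows),
                 elimination_order = elim[-length(elim)],
                 dominance = rev(elim), baseline_R = baseline,
                 mode = if (use_recurrent) "RNN" else "ANN"),
            class = "sensitivity_report")
}
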