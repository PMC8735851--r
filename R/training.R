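#' Mean squared error over samples and channels
#'
#' @param targets,predictions numeric matrices of equal shape (warm-up
#'   samples already excluded).
#' @return mean of squared errors, a single non-negative number.
#' @export
mse <- function(targets, predictions) {
  targets <- as.matrix(targets); predictions <- as.matrix(predictions)
  if (!identical(dim(targets), dim(predictions)))
    imnet_stop("targets and predictions must have identical shape",
               "imnet_shape_error")
  mean((targets - predictions)^2)
}

#' Regression R between targets and predictions
#'
#' 100 times the Pearson correlation between the flattened target and
#' prediction matrices - the mapping-performance metric used throughout the
#' model selection and evaluation stages.
#'
#' @inheritParams mse
#' @return R in percent (perfect predictions give 100).
#' @export
regression_R <- function(targets, predictions) {
  targets <- as.matrix(targets); predictions <- as.matrix(predictions)
  if (!identical(dim(targets), dim(predictions)))
    imnet_stop("targets and predictions must have identical shape",
               "imnet_shape_error")
  t_ <- as.numeric(targets); p_ <- as.numeric(predictions)
  if (stats::sd(t_) == 0 || stats::sd(p_) == 0)
    imnet_stop("regression R undefined: zero variance", "imnet_metric_error")
  100 * stats::cor(t_, p_)
}

#' Levenberg-Marquardt training settings
#'
#' Defaults follow standard LM backpropagation practice for this model
#' family: initial damping 0.001, decrease factor 0.1, increase factor 10,
#' maximum damping 1e10, at most 200 epochs, and early stopping after 100
#' epochs without a new best validation MSE.
#'
#' @param mu_init,mu_dec,mu_inc,mu_max adaptive damping schedule.
#' @param max_epochs maximum number of accepted epochs.
#' @param patience_epochs epochs without a new validation best before
#'   stopping.
#' @param goal_mse stop once training MSE falls to this value (0 = off).
#' @param max_time_s wall-clock cap in seconds (Inf = off).
#' @param standardize_inputs estimate per-column input standardization from
#'   the training windows (recommended; raw biomechanical channels have very
#'   different scales).
#' @param seed RNG seed (controls nothing inside LM itself, recorded for
#'   provenance).
#' @return a `train_settings` list.
#' @export
train_settings <- function(mu_init = 0.001, mu_dec = 0.1, mu_inc = 10,
                           mu_max = 1e10, max_epochs = 200L,
                           patience_epochs = 100L, goal_mse = 0,
                           max_time_s = Inf, standardize_inputs = TRUE,
                           seed = 1L) {
  if (!(mu_dec > 0 && mu_dec < 1 && mu_inc > 1))
    imnet_stop("need 0 < mu_dec < 1 < mu_inc", "imnet_parameter_error")
  if (mu_init <= 0 || mu_init > mu_max)
    imnet_stop("need 0 < mu_init <= mu_max", "imnet_parameter_error")
  if (patience_epochs > max_epochs)
    imnet_stop("patience must not exceed max_epochs", "imnet_parameter_error")
  structure(list(mu_init = mu_init, mu_dec = mu_dec, mu_inc = mu_inc,
                 mu_max = mu_max, max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 goal_mse = goal_mse, max_time_s = max_time_s,
                 standardize_inputs = isTRUE(standardize_inputs),
                 seed = as.integer(seed)),
            class = "train_settings")
}

# normalize data into a list of trials, each list(inputs, targets) matrices
as_trials <- function(data) {
  if (is.null(data)) return(NULL)
  if (!is.null(data$inputs)) data <- list(data)
  lapply(data, function(tr) {
    inp <- tr$inputs; tgt <- tr$targets
    if (inherits(inp, "mcts")) inp <- inp$values
    if (inherits(tgt, "mcts")) tgt <- tgt$values
    list(inputs = as.matrix(inp), targets = as.matrix(tgt))
  })
}

# stack delay windows and aligned targets over trials
collect_windows <- function(cfg, trials) {
  Xs <- list(); Ys <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    Xs[[i]] <- build_windows(cfg, tr$inputs, tr$targets)
    w <- narx_warmup(cfg)
    Ys[[i]] <- tr$targets[(w + 1L):nrow(tr$targets), , drop = FALSE]
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

# Residual Jacobian of the teacher-forced network by backpropagation.
# Rows are ordered as as.numeric(pred - Y): output-channel blocks of N.
# Columns follow flatten_params order.
narx_jacobian <- function(model, X) {
  cfg <- model$config
  fw <- narx_mlp_forward(model, X, keep = TRUE)
  N <- nrow(X)
  d <- narx_input_dim(cfg)
  P <- count_parameters(cfg)
  nn <- cfg$n_n; no <- cfg$n_outputs; nl <- cfg$n_l
  off_IW <- 0L
  off_b1 <- nn * d
  off_LW <- off_b1 + nn
  lw_size <- nn^2 + nn
  off_OW <- off_LW + (nl - 1L) * lw_size
  off_b2 <- off_OW + no * nn
  J <- matrix(0, N * no, P)
  lo <- cfg$output_range[1L]; hi <- cfg$output_range[2L]
  for (k in seq_len(no)) {
    rows <- ((k - 1L) * N + 1L):(k * N)
    m <- as.numeric(fw$lin[, k] > lo & fw$lin[, k] < hi)
    # output layer: weight (k, j) at off_OW + (j-1)*no + k; bias k
    J[rows, off_OW + (seq_len(nn) - 1L) * no + k] <- fw$acts[[nl]] * m
    J[rows, off_b2 + k] <- m
    G <- outer(m, model$OW[k, ])                     # N x nn
    for (l in rev(seq_len(nl))) {
      D <- G * hidden_act_deriv(fw$acts[[l]], cfg$hidden_activation)
      prev <- if (l == 1L) fw$Xs else fw$acts[[l - 1L]]
      dp <- ncol(prev)
      blk_off <- if (l == 1L) off_IW else off_LW + (l - 2L) * lw_size
      b_off <- if (l == 1L) off_b1 else blk_off + nn * nn
      # weight (j, i) at blk_off + (i-1)*n_row + j, n_row = nn
      J[rows, blk_off + seq_len(nn * dp)] <-
        prev[, rep(seq_len(dp), each = nn), drop = FALSE] *
        D[, rep(seq_len(nn), dp), drop = FALSE]
      J[rows, b_off + seq_len(nn)] <- D
      if (l > 1L) G <- D %*% model$LW[[l - 1L]]$W
    }
  }
  list(J = J, pred = fw$pred)
}

# shared early-stopping decision: "continue", "patience" or "max_epochs"
es_check <- function(val_history, patience, max_epochs) {
  e <- length(val_history)
  best <- which.min(val_history)
  if (e - best >= patience) return("patience")
  if (e >= max_epochs) return("max_epochs")
  "continue"
}

#' Replay a validation-MSE history through the early-stopping rule
#'
#' Feeds a recorded per-epoch validation MSE trace through the same
#' stopping decision [lm_train] uses, returning where training would halt.
#' With the best validation at epoch e and patience p, training stops at
#' epoch e + p (or at `max_epochs` if that comes first).
#'
#' @param val_mse numeric vector of per-epoch validation MSE.
#' @param patience_epochs,max_epochs stopping parameters.
#' @return list with `stop_epoch`, `best_epoch`, `stop_reason`.
#' @export
replay_early_stopping <- function(val_mse, patience_epochs = 100L,
                                  max_epochs = length(val_mse)) {
  for (e in seq_along(val_mse)) {
    reason <- es_check(val_mse[seq_len(e)], patience_epochs, max_epochs)
    if (reason != "continue")
      return(list(stop_epoch = e,
                  best_epoch = which.min(val_mse[seq_len(e)]),
                  stop_reason = reason))
  }
  list(stop_epoch = length(val_mse),
       best_epoch = which.min(val_mse), stop_reason = "exhausted")
}

#' Train a NARX model with Levenberg-Marquardt backpropagation
#'
#' Teacher-forced (open-loop) training: given the delay windows the network
#' is feedforward, so each epoch builds the full residual vector `e` and its
#' analytic Jacobian `J` by backpropagation and takes the damped
#' Gauss-Newton step `delta = -(J'J + mu I)^{-1} J'e`. A step is accepted
#' only if it lowers the training MSE, in which case `mu` is multiplied by
#' `mu_dec`; otherwise `mu` is multiplied by `mu_inc` and the step is
#' retried, aborting the run when `mu` exceeds `mu_max`. Validation MSE is
#' recorded per accepted epoch; training stops after `patience_epochs`
#' epochs without a new validation best, at `max_epochs`, at `goal_mse`, or
#' on the damping/time caps. The returned model carries the weights of the
#' best validation epoch, not the last one.
#'
#' @param model a `narx_model` (see [init_model]).
#' @param train_data,val_data,test_data trial lists: each trial is a list
#'   with `inputs` (T x n_inputs) and `targets` (T x n_outputs), as matrices
#'   or [mcts] objects. A bare `list(inputs=, targets=)` is also accepted.
#'   `test_data` is optional and only monitored.
#' @param settings a [train_settings].
#' @param n_starts number of random initializations. LM on a sigmoid
#'   network is a local optimizer and occasionally lands in a poor basin;
#'   with `n_starts > 1` a select-then-continue schedule is used: every
#'   start (the given model plus fresh initializations with seeds derived
#'   from `settings$seed`) trains for a short probe of `select_epochs`
#'   epochs, the start with the best validation MSE continues with the
#'   remaining epoch budget, and `max_epochs` caps the TOTAL number of
#'   accepted epochs across all phases. This is the standard multi-start
#'   practice for damped Gauss-Newton network training, with the budget
#'   kept explicit. Remaining starts are skipped once a probe reaches
#'   `goal_mse`.
#' @param select_epochs probe length per start (default
#'   `max_epochs / (2 * n_starts)`, at least 5).
#' @return list with `model` (weights restored to the best validation
#'   epoch), `history` (data frame: start, epoch, train_mse, val_mse,
#'   test_mse, mu), `best_epoch`, and `stop_reason` (one of `patience`,
#'   `max_epochs`, `goal`, `mu_max`, `time`).
#' @export
lm_train <- function(model, train_data, val_data, test_data = NULL,
                     settings = train_settings(), n_starts = 1L,
                     select_epochs = NULL) {
  stopifnot(inherits(model, "narx_model"), inherits(settings, "train_settings"))
  if (n_starts <= 1L) {
    fit <- lm_train_single(model, train_data, val_data, test_data, settings)
    fit$history$start <- rep_len(1L, nrow(fit$history))
    fit$best_start <- 1L
    return(fit)
  }
  if (is.null(select_epochs))
    select_epochs <- max(5L, settings$max_epochs %/% (2L * n_starts))
  probe <- settings
  probe$max_epochs <- as.integer(select_epochs)
  probe$patience_epochs <- min(probe$patience_epochs, probe$max_epochs)
  fits <- vector("list", n_starts)
  used <- 0L
  for (s in seq_len(n_starts)) {
    m_s <- if (s == 1L) model
           else init_model(model$config, derive_seed(settings$seed, s, 4L))
    fits[[s]] <- lm_train_single(m_s, train_data, val_data, test_data, probe)
    fits[[s]]$history$start <- rep_len(s, nrow(fits[[s]]$history))
    used <- used + nrow(fits[[s]]$history)
    if (fits[[s]]$stop_reason == "goal") break
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  win <- which.min(vapply(fits, function(f) f$best_val, numeric(1)))
  out <- fits[[win]]
  remaining <- settings$max_epochs - used
  if (remaining > 0L && out$stop_reason != "goal") {
    cont <- settings
    cont$max_epochs <- as.integer(remaining)
    cont$patience_epochs <- min(cont$patience_epochs, cont$max_epochs)
    out2 <- lm_train_single(out$model, train_data, val_data, test_data, cont)
    out2$history$start <- rep_len(win, nrow(out2$history))
    if (out2$best_val <= out$best_val) {
      out2$history <- rbind(out$history, out2$history)
      out2$best_start <- win
      out2$history <- do.call(rbind, c(lapply(fits[-win], `[[`, "history"),
                                       list(out2$history)))
      return(out2)
    }
  }
  out$history <- do.call(rbind, lapply(fits, `[[`, "history"))
  out$best_start <- win
  out
}

lm_train_single <- function(model, train_data, val_data, test_data,
                            settings) {
  cfg <- model$config
  tr <- collect_windows(cfg, as_trials(train_data))
  va <- collect_windows(cfg, as_trials(val_data))
  te <- if (!is.null(test_data)) collect_windows(cfg, as_trials(test_data))
  P <- count_parameters(cfg)
  n_resid <- nrow(tr$X) * cfg$n_outputs
  if (P >= n_resid)
    warning(sprintf("under-determined fit: %d parameters, %d residuals",
                    P, n_resid), call. = FALSE)
  if (settings$standardize_inputs) {
    ctr <- colMeans(tr$X)
    scl <- apply(tr$X, 2L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    model$in_center <- ctr
    model$in_scale <- scl
  }
  w <- flatten_params(model)
  mu <- settings$mu_init
  t0 <- proc.time()[["elapsed"]]
  hist_rows <- vector("list", settings$max_epochs)
  best <- list(epoch = 0L, val = Inf, w = w)
  stop_reason <- "max_epochs"
  val_hist <- numeric(0)
  train_mse_of <- function(wv) {
    m2 <- unflatten_params(model, wv)
    mse(tr$Y, narx_mlp_forward(m2, tr$X))
  }
  epoch <- 0L
  while (epoch < settings$max_epochs) {
    jb <- narx_jacobian(unflatten_params(model, w), tr$X)
    if (!all(is.finite(jb$pred)))
      imnet_stop("non-finite residuals during training", "imnet_numeric_error")
    r <- as.numeric(jb$pred - tr$Y)
    mse_cur <- mean(r^2)
    JtJ <- crossprod(jb$J)
    g <- crossprod(jb$J, r)
    accepted <- FALSE
    while (mu <= settings$mu_max) {
      step <- tryCatch(
        -solve(JtJ + diag(mu, P), g),
        error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        w_try <- w + as.numeric(step)
        mse_try <- train_mse_of(w_try)
        if (is.finite(mse_try) && mse_try < mse_cur) {
          w <- w_try
          mu <- max(mu * settings$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * settings$mu_inc
    }
    if (!accepted) { stop_reason <- "mu_max"; break }
    epoch <- epoch + 1L
    m_now <- unflatten_params(model, w)
    tr_mse <- train_mse_of(w)
    va_mse <- mse(va$Y, narx_mlp_forward(m_now, va$X))
    te_mse <- if (!is.null(te)) mse(te$Y, narx_mlp_forward(m_now, te$X)) else NA_real_
    hist_rows[[epoch]] <- data.frame(epoch = epoch, train_mse = tr_mse,
                                     val_mse = va_mse, test_mse = te_mse,
                                     mu = mu)
    val_hist[epoch] <- va_mse
    if (va_mse < best$val) best <- list(epoch = epoch, val = va_mse, w = w)
    if (settings$goal_mse > 0 && tr_mse <= settings$goal_mse) {
      stop_reason <- "goal"; break
    }
    reason <- es_check(val_hist, settings$patience_epochs, settings$max_epochs)
    if (reason != "continue") { stop_reason <- reason; break }
    if (proc.time()[["elapsed"]] - t0 > settings$max_time_s) {
      stop_reason <- "time"; break
    }
  }
  history <- if (epoch > 0L) do.call(rbind, hist_rows[seq_len(epoch)])
             else data.frame(epoch = integer(0), train_mse = numeric(0),
                             val_mse = numeric(0), test_mse = numeric(0),
                             mu = numeric(0))
  out_model <- unflatten_params(model, best$w)
  structure(list(model = out_model, history = history,
                 best_epoch = best$epoch, best_val = best$val,
                 stop_reason = stop_reason),
            class = "narx_fit")
}

#' Export a training history as delimited text
#'
#' @param fit a `narx_fit` from [lm_train].
#' @param path output CSV path.
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}

#' Subject-level train/validation/test split
#'
#' Partitions a cohort at the subject level (no subject's trials straddle
#' blocks), deterministically per seed. The default 14/2/1 split matches a
#' 17-subject cohort.
#'
#' @param cohort list of subject datasets (see [generate_cohort]).
#' @param n_train,n_val,n_test block sizes.
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` (subject lists) and `indices`.
#' @export
subject_split <- function(cohort, n_train = 14L, n_val = 2L, n_test = 1L,
                          seed = 1L) {
  n <- length(cohort)
  if (n < n_train + n_val + n_test)
    imnet_stop(sprintf("cohort has %d subjects; split needs %d", n,
                       n_train + n_val + n_test), "imnet_data_error")
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  list(train = cohort[idx$train], val = cohort[idx$val],
       test = cohort[idx$test], indices = idx)
}

#' Pool all trials of a list of subject datasets
#'
#' @param subjects list of subject datasets.
#' @return flat list of trials suitable for [lm_train].
#' @export
subject_trials <- function(subjects) {
  do.call(c, lapply(subjects, function(s) s$trials))
}
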