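#' NARX network configuration
#'
#' Architecture hyperparameters of the nonlinear autoregressive network with
#' exogenous inputs. The tap convention (stated here once, used everywhere):
#' the input tapped delay line holds exactly `n_u` vectors
#' `u(t), u(t-1), ..., u(t-n_u+1)` (the current sample included) and the
#' feedback delay line holds exactly `n_y` strictly-previous output vectors
#' `y(t-1), ..., y(t-n_y)`. This convention is the one under which the
#' parameter-count formula of [count_parameters] and the delay-window
#' durations of [delay_window_duration] are mutually consistent (e.g.
#' n_u = 3, n_y = 5 at 50 Hz give 0.06 s and 0.1 s windows). `n_y = 0`
#' disables feedback entirely, turning the model into a plain feedforward
#' (ANN) mapping - used by the sensitivity analysis.
#'
#' @param n_inputs number of external input channels.
#' @param n_outputs number of output channels.
#' @param n_l number of hidden layers (>= 1).
#' @param n_n nodes per hidden layer.
#' @param n_u input delay taps (>= 1, current sample included).
#' @param n_y feedback delay taps (>= 0; 0 = feedforward ANN).
#' @param hidden_activation `"logistic_sigmoid"` (default), `"tanh"`, or
#'   `"identity"`.
#' @param output_range saturation range of the linear output activation;
#'   default c(0, 1) matching normalized EMG envelopes. Use
#'   `c(-Inf, Inf)` for a purely linear output.
#' @return a `narx_config` list.
#' @export
narx_config <- function(n_inputs, n_outputs, n_l = 1L, n_n = 20L, n_u = 3L,
                        n_y = 5L,
                        hidden_activation = c("logistic_sigmoid", "tanh",
                                              "identity"),
                        output_range = c(0, 1)) {
  hidden_activation <- match.arg(hidden_activation)
  if (n_inputs < 1L || n_outputs < 1L || n_l < 1L || n_n < 1L || n_u < 1L ||
      n_y < 0L)
    imnet_stop("invalid NARX configuration counts", "imnet_parameter_error")
  if (output_range[1L] >= output_range[2L])
    imnet_stop("output_range must be increasing", "imnet_parameter_error")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs), n_l = as.integer(n_l),
                 n_n = as.integer(n_n), n_u = as.integer(n_u),
                 n_y = as.integer(n_y),
                 hidden_activation = hidden_activation,
                 output_range = as.numeric(output_range)),
            class = "narx_config")
}

narx_input_dim <- function(cfg) cfg$n_inputs * cfg$n_u + cfg$n_outputs * cfg$n_y

#' Count trainable parameters of a NARX configuration
#'
#' For one hidden layer:
#' `n_n * (n_inputs*n_u + n_outputs*n_y) + n_n + n_outputs*n_n + n_outputs`
#' (first-layer weights and biases plus the fully connected output layer);
#' each additional hidden layer adds `n_n^2 + n_n`.
#'
#' @param cfg a [narx_config].
#' @return integer parameter count.
#' @examples
#' count_parameters(narx_config(5, 6, n_l = 1, n_n = 20, n_u = 3, n_y = 5))
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "narx_config"))
  d <- narx_input_dim(cfg)
  as.integer(cfg$n_n * d + cfg$n_n + (cfg$n_l - 1L) * (cfg$n_n^2 + cfg$n_n) +
               cfg$n_outputs * cfg$n_n + cfg$n_outputs)
}

#' Duration of the tapped delay windows
#'
#' @param cfg a [narx_config].
#' @param sample_rate_hz sampling rate of the signals (Hz).
#' @return named numeric: `input_s = n_u/rate`, `feedback_s = n_y/rate`.
#' @export
delay_window_duration <- function(cfg, sample_rate_hz) {
  if (sample_rate_hz <= 0)
    imnet_stop("sample rate must be positive", "imnet_parameter_error")
  c(input_s = cfg$n_u / sample_rate_hz, feedback_s = cfg$n_y / sample_rate_hz)
}

#' Initialize a NARX model
#'
#' Weights are drawn uniformly from [-0.5, 0.5] scaled by 1/sqrt(fan-in);
#' hidden biases start at zero and the output bias at the center of the
#' saturation range (0.5 for the default [0, 1] output), so the initial
#' outputs sit inside the linear region of the saturating activation - a
#' network initialized into full saturation has an identically zero error
#' gradient and cannot train. Deterministic per seed. Input standardization
#' is initialized to the identity (center 0, scale 1) and is normally
#' replaced by training-set statistics in [lm_train].
#'
#' @param cfg a [narx_config].
#' @param seed integer RNG seed.
#' @return a `narx_model` list: `config`, first-layer weights `IW`
#'   (n_n x input dim) with bias `b1`, per-extra-layer weights `LW` (list of
#'   `W`, `b`), output weights `OW` (n_outputs x n_n) with bias `b2`, and the
#'   input standardization (`in_center`, `in_scale`).
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "narx_config"))
  rng <- with_seed(seed, {
    d <- narx_input_dim(cfg)
    IW <- matrix(stats::runif(cfg$n_n * d, -0.5, 0.5) / sqrt(d), cfg$n_n, d)
    LW <- if (cfg$n_l > 1L)
      lapply(seq_len(cfg$n_l - 1L), function(i)
        list(W = matrix(stats::runif(cfg$n_n^2, -0.5, 0.5) / sqrt(cfg$n_n),
                        cfg$n_n, cfg$n_n),
             b = rep(0, cfg$n_n)))
    else list()
    OW <- matrix(stats::runif(cfg$n_outputs * cfg$n_n, -0.5, 0.5) /
                   sqrt(cfg$n_n), cfg$n_outputs, cfg$n_n)
    list(IW = IW, LW = LW, OW = OW)
  })
  b2_0 <- if (all(is.finite(cfg$output_range))) mean(cfg$output_range) else 0
  structure(list(config = cfg, IW = rng$IW, b1 = rep(0, cfg$n_n),
                 LW = rng$LW, OW = rng$OW, b2 = rep(b2_0, cfg$n_outputs),
                 in_center = rep(0, narx_input_dim(cfg)),
                 in_scale = rep(1, narx_input_dim(cfg))),
            class = "narx_model")
}

hidden_act <- function(z, kind) switch(kind,
  logistic_sigmoid = 1 / (1 + exp(-z)),
  tanh = tanh(z),
  identity = z)

hidden_act_deriv <- function(a, kind) switch(kind,
  logistic_sigmoid = a * (1 - a),
  tanh = 1 - a^2,
  identity = array(1, dim(a)))

satlin <- function(x, range) pmin(pmax(x, range[1L]), range[2L])

# Forward pass of the underlying MLP on a matrix of delay-window rows.
# Returns predictions and, if keep = TRUE, pre/post-activation caches for
# the Jacobian.
narx_mlp_forward <- function(model, X, keep = FALSE) {
  cfg <- model$config
  Xs <- sweep(sweep(X, 2L, model$in_center, "-"), 2L, model$in_scale, "/")
  acts <- vector("list", cfg$n_l)
  a <- hidden_act(Xs %*% t(model$IW) + rep(model$b1, each = nrow(Xs)),
                  cfg$hidden_activation)
  acts[[1L]] <- a
  if (cfg$n_l > 1L) for (i in seq_len(cfg$n_l - 1L)) {
    a <- hidden_act(a %*% t(model$LW[[i]]$W) +
                      rep(model$LW[[i]]$b, each = nrow(a)),
                    cfg$hidden_activation)
    acts[[i + 1L]] <- a
  }
  lin <- a %*% t(model$OW) + rep(model$b2, each = nrow(a))
  pred <- satlin(lin, cfg$output_range)
  if (keep) list(pred = pred, lin = lin, acts = acts, Xs = Xs) else pred
}

narx_warmup <- function(cfg) max(cfg$n_u - 1L, cfg$n_y)

# Build the delay-window design matrix for one trial. inputs: T x n_inputs,
# feedback: T x n_outputs (measured targets for open loop). Rows correspond
# to t = warmup+1 .. T.
build_windows <- function(cfg, inputs, feedback) {
  T_ <- nrow(inputs)
  w <- narx_warmup(cfg)
  if (T_ <= w)
    imnet_stop(sprintf("trial too short: %d samples, warm-up %d", T_, w),
               "imnet_data_error")
  t_idx <- (w + 1L):T_
  ucols <- lapply(seq_len(cfg$n_u) - 1L, function(lag)
    inputs[t_idx - lag, , drop = FALSE])
  ycols <- if (cfg$n_y > 0L)
    lapply(seq_len(cfg$n_y), function(lag)
      feedback[t_idx - lag, , drop = FALSE])
  else list()
  do.call(cbind, c(ucols, ycols))
}

#' Open-loop (teacher-forced) NARX evaluation
#'
#' Series-parallel mode: the feedback taps are filled from the measured
#' targets, which makes the network a feedforward map of the delay windows.
#' The first `max(n_u - 1, n_y)` samples of a trial are warm-up and excluded,
#' so the returned series has `T - warmup` rows (aligned to
#' `t = warmup+1 .. T`).
#'
#' @param model a `narx_model`.
#' @param inputs numeric matrix `T x n_inputs` of external inputs.
#' @param targets numeric matrix `T x n_outputs` of measured outputs.
#' @return predictions, `(T - warmup) x n_outputs`, clipped to the output
#'   range.
#' @export
forward_open_loop <- function(model, inputs, targets) {
  cfg <- model$config
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (ncol(inputs) != cfg$n_inputs || ncol(targets) != cfg$n_outputs ||
      nrow(inputs) != nrow(targets))
    imnet_stop("input/target shapes do not match the configuration",
               "imnet_shape_error")
  X <- build_windows(cfg, inputs, targets)
  narx_mlp_forward(model, X)
}

#' Closed-loop (self-feedback) NARX evaluation
#'
#' Parallel mode: identical computation to [forward_open_loop] except that
#' the feedback taps hold the model's own previous predictions. This is the
#' deployment mode - EMG envelopes are estimated from biomechanical inputs
#' alone. `initial_feedback` seeds the feedback delay line for the first
#' predicted step; the default zero matrix matches deployment, where no
#' measured EMG exists.
#'
#' @param model a `narx_model`.
#' @param inputs numeric matrix `T x n_inputs`.
#' @param initial_feedback `n_y x n_outputs` matrix: rows are
#'   `y(t0-1), y(t0-2), ..., y(t0-n_y)` (most recent first), where
#'   `t0 = warmup + 1` is the first predicted step. Default all zeros.
#' @return predictions, `(T - warmup) x n_outputs`.
#' @export
forward_closed_loop <- function(model, inputs,
                                initial_feedback = NULL) {
  cfg <- model$config
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != cfg$n_inputs)
    imnet_stop("input width does not match the configuration",
               "imnet_shape_error")
  T_ <- nrow(inputs)
  w <- narx_warmup(cfg)
  if (T_ <= w)
    imnet_stop("trial too short for the delay windows", "imnet_data_error")
  if (cfg$n_y == 0L)  # feedforward: no feedback to roll
    return(forward_open_loop(model, inputs,
                             matrix(0, T_, cfg$n_outputs)))
  if (is.null(initial_feedback))
    initial_feedback <- matrix(0, cfg$n_y, cfg$n_outputs)
  initial_feedback <- as.matrix(initial_feedback)
  if (nrow(initial_feedback) != cfg$n_y ||
      ncol(initial_feedback) != cfg$n_outputs)
    imnet_stop("initial_feedback must be n_y x n_outputs", "imnet_shape_error")
  t_idx <- (w + 1L):T_
  preds <- matrix(0, length(t_idx), cfg$n_outputs)
  # feedback buffer, most recent first
  fb <- initial_feedback
  for (s in seq_along(t_idx)) {
    t <- t_idx[s]
    u <- as.numeric(t(inputs[t - (seq_len(cfg$n_u) - 1L), , drop = FALSE]))
    x <- c(u, as.numeric(t(fb)))
    preds[s, ] <- narx_mlp_forward(model, matrix(x, 1L))
    fb <- rbind(preds[s, , drop = FALSE],
                fb[-cfg$n_y, , drop = FALSE])
  }
  preds
}

# --- parameter vector plumbing (order: IW, b1, LW/b per layer, OW, b2) ----

flatten_params <- function(model) {
  c(as.numeric(model$IW), model$b1,
    unlist(lapply(model$LW, function(l) c(as.numeric(l$W), l$b))),
    as.numeric(model$OW), model$b2)
}

unflatten_params <- function(model, w) {
  cfg <- model$config
  d <- narx_input_dim(cfg)
  i <- 0L
  take <- function(n) { v <- w[(i + 1L):(i + n)]; i <<- i + n; v }
  model$IW <- matrix(take(cfg$n_n * d), cfg$n_n, d)
  model$b1 <- take(cfg$n_n)
  if (cfg$n_l > 1L) for (k in seq_len(cfg$n_l - 1L)) {
    model$LW[[k]]$W <- matrix(take(cfg$n_n^2), cfg$n_n, cfg$n_n)
    model$LW[[k]]$b <- take(cfg$n_n)
  }
  model$OW <- matrix(take(cfg$n_outputs * cfg$n_n), cfg$n_outputs, cfg$n_n)
  model$b2 <- take(cfg$n_outputs)
  stopifnot(i == length(w))
  model
}

#' Save or load a NARX model as portable text
#'
#' The archive is a single JSON file holding the configuration, the weight
#' arrays and the input standardization at full double precision
#' (round trips are bit-exact).
#'
#' @param model a `narx_model`.
#' @param path file path.
#' @export
save_narx <- function(model, path) {
  stopifnot(inherits(model, "narx_model"))
  enc <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(
    format = "imnet-narx-1",
    config = unclass(model$config),
    dims = list(IW = dim(model$IW), OW = dim(model$OW)),
    IW = enc(model$IW), b1 = enc(model$b1),
    LW = lapply(model$LW, function(l) list(W = enc(l$W), b = enc(l$b))),
    OW = enc(model$OW), b2 = enc(model$b2),
    in_center = enc(model$in_center), in_scale = enc(model$in_scale))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_narx
#' @export
load_narx <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "imnet-narx-1")
    imnet_stop("not an imnet NARX model archive", "imnet_parse_error")
  cfgl <- obj$config
  cfg <- narx_config(cfgl$n_inputs, cfgl$n_outputs, cfgl$n_l, cfgl$n_n,
                     cfgl$n_u, cfgl$n_y, cfgl$hidden_activation,
                     as.numeric(cfgl$output_range))
  dec <- function(x) as.numeric(x)
  LW <- list()
  if (length(obj$LW) > 0L) {
    # jsonlite may simplify the list of layers to a data frame
    if (is.data.frame(obj$LW)) {
      LW <- lapply(seq_len(nrow(obj$LW)), function(i)
        list(W = matrix(dec(obj$LW$W[[i]]), cfg$n_n, cfg$n_n),
             b = dec(obj$LW$b[[i]])))
    } else {
      LW <- lapply(obj$LW, function(l)
        list(W = matrix(dec(l$W), cfg$n_n, cfg$n_n), b = dec(l$b)))
    }
  }
  structure(list(config = cfg,
                 IW = matrix(dec(obj$IW), obj$dims$IW[1L], obj$dims$IW[2L]),
                 b1 = dec(obj$b1), LW = LW,
                 OW = matrix(dec(obj$OW), obj$dims$OW[1L], obj$dims$OW[2L]),
                 b2 = dec(obj$b2), in_center = dec(obj$in_center),
                 in_scale = dec(obj$in_scale)),
            class = "narx_model")
}
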