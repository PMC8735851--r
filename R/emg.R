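#' EMG filter chain settings
#'
#' Settings of the raw-EMG to activation-envelope conversion. The
#' `seven_step` preset is the full chain: (1) band-pass, (2) band-stop for
#' mains interference, (3) full-wave rectification, (4) envelope low-pass,
#' (5) per-trial, per-channel maximum normalization, (6) cubic resampling to
#' the kinematic rate, (7) exponential shaping toward activation-like
#' dynamics. The `three_step` preset is the minimal chain: high-pass,
#' rectify, low-pass (then the same normalization and resampling so the
#' output contract is identical).
#'
#' @param bandpass numeric pair (low, high) Hz; default c(20, 500).
#' @param bandstop numeric pair around the mains frequency; default c(55, 65).
#' @param envelope_lowpass_hz envelope smoothing cutoff; default 7.
#' @param target_rate_hz output rate; default 50.
#' @param shape_factor exponential shaping factor A in [-3, 3]; 0 disables
#'   shaping. Default -1.
#' @param preset `"seven_step"` or `"three_step"`.
#' @param highpass_hz,lowpass_hz the three-step preset's cutoffs (70, 10).
#' @param order Butterworth order for every stage.
#' @return an `emg_filter_settings` list.
#' @export
emg_filter_settings <- function(bandpass = c(20, 500), bandstop = c(55, 65),
                                envelope_lowpass_hz = 7, target_rate_hz = 50,
                                shape_factor = -1,
                                preset = c("seven_step", "three_step"),
                                highpass_hz = 70, lowpass_hz = 10,
                                order = 4L) {
  preset <- match.arg(preset)
  if (bandpass[1L] <= 0 || bandpass[1L] >= bandpass[2L] ||
      bandstop[1L] <= 0 || bandstop[1L] >= bandstop[2L])
    imnet_stop("band edges must satisfy 0 < low < high",
               "imnet_parameter_error")
  if (abs(shape_factor) > 3)
    imnet_stop("shape_factor must lie in [-3, 3]", "imnet_parameter_error")
  if (target_rate_hz <= 2 * envelope_lowpass_hz)
    imnet_stop("target rate must exceed twice the envelope cutoff",
               "imnet_parameter_error")
  structure(list(bandpass = bandpass, bandstop = bandstop,
                 envelope_lowpass_hz = envelope_lowpass_hz,
                 target_rate_hz = target_rate_hz, shape_factor = shape_factor,
                 preset = preset, highpass_hz = highpass_hz,
                 lowpass_hz = lowpass_hz, order = as.integer(order)),
            class = "emg_filter_settings")
}

#' Exponential activation shaping function
#'
#' Maps a normalized envelope through
#' `a(u) = (exp(A u) - 1) / (exp(A) - 1)` (identity for A = 0), a strictly
#' increasing bijection of [0, 1] with fixed endpoints. Negative A bends the
#' curve upward, mimicking the nonlinear EMG-to-activation relation of
#' biomechanical muscle models.
#'
#' @param u numeric in [0, 1]; vectorized.
#' @param A shaping factor, typically in [-3, 3].
#' @return shaped values in [0, 1].
#' @export
shaping_function <- function(u, A) {
  if (any(u < 0 | u > 1, na.rm = TRUE))
    imnet_stop("shaping_function input must lie in [0, 1]", "imnet_domain_error")
  if (A == 0) return(u)
  (exp(A * u) - 1) / (exp(A) - 1)
}

# characteristic (slowest) frequency of each stage governs the edge-pad
# length of the zero-phase filter: cutoff for low/high-pass, the narrower
# of band edge and bandwidth for band filters
zero_phase <- function(x, bf, f_char_norm) zp_filter(bf, x, f_char_norm)

#' Convert raw EMG to normalized activation envelopes
#'
#' Applies the selected filter-chain preset (see [emg_filter_settings])
#' channel-wise and returns a 50 Hz (by default) envelope bounded in [0, 1]
#' with per-trial, per-channel maximum exactly 1. All filters are zero-phase
#' Butterworth, so envelope timing stays aligned with the kinematic
#' channels. Negative post-filter ripple is clipped to 0 before
#' normalization; after the cubic resample the envelope is re-clipped and
#' re-normalized so the unit-maximum contract holds exactly at the output
#' rate. The first and last 0.25 s carry zero-phase edge transients and
#' should be trimmed before quantitative use (`edge_trim_s` attribute).
#'
#' @param raw [mcts] of raw EMG, sampled well above the band-pass high edge
#'   (1500 Hz in the recording protocol this chain targets). If the rate is
#'   too low the high edge is clamped with a warning.
#' @param settings an [emg_filter_settings].
#' @param return_stages if TRUE, also return the intermediate stage signals
#'   (at the input rate) for diagnostics.
#' @return [mcts] at `target_rate_hz`, values in [0, 1]; with
#'   `return_stages = TRUE`, a list `(envelope, stages)`.
#' @export
filter_emg_chain <- function(raw, settings = emg_filter_settings(),
                             return_stages = FALSE) {
  stopifnot(inherits(raw, "mcts"), inherits(settings, "emg_filter_settings"))
  fs <- raw$rate_hz
  nyq <- fs / 2
  dur <- n_samples(raw) / fs
  if (dur < 1)
    imnet_stop("EMG trial shorter than 1 s", "imnet_data_error")
  ord <- settings$order
  stages <- list()
  x <- raw$values
  if (settings$preset == "seven_step") {
    hi <- settings$bandpass[2L]
    if (hi >= nyq) {
      hi <- 0.9 * nyq
      warning(sprintf("band-pass high edge clamped to %g Hz (Nyquist %g Hz)",
                      hi, nyq), call. = FALSE)
    }
    bp <- signal::butter(ord, c(settings$bandpass[1L], hi) / nyq, type = "pass")
    bs <- signal::butter(ord, settings$bandstop / nyq, type = "stop")
    f_bp <- min(settings$bandpass[1L], hi - settings$bandpass[1L]) / nyq
    f_bs <- diff(settings$bandstop) / nyq
    x <- apply(x, 2L, zero_phase, bf = bp, f_char_norm = f_bp)
    stages$bandpassed <- x
    x <- apply(x, 2L, zero_phase, bf = bs, f_char_norm = f_bs)
    stages$bandstopped <- x
    x <- abs(x);                             stages$rectified <- x
  } else {
    hp <- signal::butter(ord, settings$highpass_hz / nyq, type = "high")
    x <- apply(x, 2L, zero_phase, bf = hp,
               f_char_norm = settings$highpass_hz / nyq)
    stages$highpassed <- x
    x <- abs(x);                             stages$rectified <- x
  }
  env_cut <- if (settings$preset == "seven_step") settings$envelope_lowpass_hz
             else settings$lowpass_hz
  lp <- signal::butter(ord, env_cut / nyq, type = "low")
  x <- apply(x, 2L, zero_phase, bf = lp, f_char_norm = env_cut / nyq)
  x <- pmax(x, 0)
  stages$envelope <- x
  mx <- apply(x, 2L, max)
  if (any(mx <= 0))
    imnet_stop(paste0("all-zero EMG trial in channel(s): ",
                      paste(raw$channels[mx <= 0], collapse = ", ")),
               "imnet_normalization_error")
  x <- sweep(x, 2L, mx, "/")
  stages$normalized <- x
  t_in <- time_points(raw)
  t_out <- seq(t_in[1L], t_in[length(t_in)], by = 1 / settings$target_rate_hz)
  y <- vapply(seq_len(ncol(x)), function(j)
    stats::spline(t_in, x[, j], xout = t_out, method = "fmm")$y,
    numeric(length(t_out)))
  if (is.vector(y)) y <- matrix(y, ncol = ncol(x))
  y <- pmin(pmax(y, 0), 1)
  y <- sweep(y, 2L, apply(y, 2L, max), "/")
  if (settings$shape_factor != 0)
    y <- shaping_function(y, settings$shape_factor)
  out <- mcts(y, settings$target_rate_hz, raw$channels, raw$start_s)
  attr(out, "edge_trim_s") <- 0.25
  if (return_stages) list(envelope = out, stages = stages) else out
}
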