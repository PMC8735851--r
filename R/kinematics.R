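# Zero-phase IIR filtering: forward and backward passes over an
# odd-reflection-padded signal, each pass started from the steady state of
# the pad's first value so step transients never enter the data. The pad
# length scales with the filter's settle time (6 periods of the slowest
# characteristic frequency), capped at the signal length.
zp_filter <- function(bf, x, f_char_norm) {
  b <- bf$b; a <- bf$a
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 / f_char_norm)) + 8L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  dc <- sum(b) / sum(a)
  run <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1L], length(b) - 1L),
                              init = rep(v[1L] * dc, length(a) - 1L)))
  }
  y <- rev(run(rev(run(xp))))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters every channel with an order-`order` Butterworth low-pass applied
#' forward and backward (`signal::filtfilt`), so the response has zero phase
#' lag and unit DC gain. Two passes square the magnitude response, so the
#' gain at the cutoff frequency is 1/2 rather than the single-pass -3 dB.
#'
#' @param ts an [mcts] time series.
#' @param cutoff_hz cutoff frequency in Hz; must lie below Nyquist.
#' @param order filter order per pass (default 4).
#' @return filtered [mcts] with the same length and rate.
#' @export
lowpass_filter <- function(ts, cutoff_hz, order = 4L) {
  stopifnot(inherits(ts, "mcts"))
  nyq <- ts$rate_hz / 2
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L ||
      cutoff_hz <= 0 || cutoff_hz >= nyq)
    imnet_stop(sprintf("cutoff %.4g Hz must be in (0, Nyquist = %.4g Hz)",
                       cutoff_hz, nyq), "imnet_parameter_error")
  if (order < 1L) imnet_stop("filter order must be >= 1", "imnet_parameter_error")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  out <- apply(ts$values, 2L, function(x) zp_filter(bf, x, cutoff_hz / nyq))
  if (is.vector(out)) out <- matrix(out, ncol = n_channels(ts))
  mcts(out, ts$rate_hz, ts$channels, ts$start_s)
}

#' Numerical differentiation of a time series
#'
#' Second-order central differences on interior samples and one-sided
#' second-order differences at the two endpoints, so the output keeps the
#' input length and stays aligned with the EMG channels.
#'
#' @param ts an [mcts] with at least 3 samples.
#' @return the sample-wise derivative, same length and rate.
#' @export
differentiate <- function(ts) {
  stopifnot(inherits(ts, "mcts"))
  n <- n_samples(ts)
  if (n < 3L)
    imnet_stop("differentiation needs at least 3 samples", "imnet_data_error")
  h <- 1 / ts$rate_hz
  x <- ts$values
  d <- matrix(0, n, ncol(x))
  d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) / (2 * h)
  d[1L, ] <- (-3 * x[1L, ] + 4 * x[2L, ] - x[3L, ]) / (2 * h)
  d[n, ] <- (3 * x[n, ] - 4 * x[n - 1L, ] + x[n - 2L, ]) / (2 * h)
  mcts(d, ts$rate_hz, ts$channels, ts$start_s)
}

axis_vec <- function(a) switch(a, X = c(1, 0, 0), Y = c(0, 1, 0), Z = c(0, 0, 1),
                               imnet_stop("axes must be X, Y or Z",
                                          "imnet_parameter_error"))

rot_axis <- function(a, q) {
  c_ <- cos(q); s <- sin(q)
  switch(a,
    X = matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3),
    Y = matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3),
    Z = matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3))
}

#' Euler-rate transformation matrix
#'
#' For an intrinsic Euler rotation sequence (default Z-X-Y) the angular
#' velocity expressed in the base frame is `omega = E(q) %*% qdot` with
#' `E(q) = [e1, R1(q1) e2, R1(q1) R2(q2) e3]`: each successive rate acts
#' about its axis rotated by the preceding elementary rotations. At q = 0,
#' E maps each Euler rate onto its own sequence axis. The map loses rank at
#' the sequence's gimbal-lock configurations.
#'
#' @param q numeric triple of Euler angles (rad).
#' @param sequence character triple of axes, no two consecutive equal.
#' @return 3x3 matrix E(q).
#' @export
euler_rate_matrix <- function(q, sequence = c("Z", "X", "Y")) {
  stopifnot(length(q) == 3L, length(sequence) == 3L)
  if (any(sequence[-1L] == sequence[-3L]))
    imnet_stop("consecutive Euler axes must differ", "imnet_parameter_error")
  r1 <- rot_axis(sequence[1L], q[1L])
  r12 <- r1 %*% rot_axis(sequence[2L], q[2L])
  cbind(axis_vec(sequence[1L]), r1 %*% axis_vec(sequence[2L]),
        r12 %*% axis_vec(sequence[3L]))
}

#' Convert Euler-angle rates to angular velocity (and back)
#'
#' @param q,qdot Euler angles and their time derivatives (rad, rad/s).
#' @param sequence axis triple, see [euler_rate_matrix].
#' @param tol singularity tolerance on `|det E|`.
#' @return angular velocity triple (rad/s); the inverse returns Euler rates.
#' @export
euler_rates_to_angular_velocity <- function(q, qdot, sequence = c("Z", "X", "Y"),
                                            tol = 1e-8) {
  E <- euler_rate_matrix(q, sequence)
  if (abs(det(E)) < tol)
    imnet_stop("Euler-rate matrix is singular at this configuration",
               "imnet_singularity_error")
  as.numeric(E %*% qdot)
}

#' @rdname euler_rates_to_angular_velocity
#' @param omega angular velocity triple (rad/s).
#' @export
angular_velocity_to_euler_rates <- function(q, omega, sequence = c("Z", "X", "Y"),
                                            tol = 1e-8) {
  E <- euler_rate_matrix(q, sequence)
  if (abs(det(E)) < tol)
    imnet_stop("Euler-rate matrix is singular at this configuration",
               "imnet_singularity_error")
  as.numeric(solve(E, omega))
}

#' Kinematic preparation pipeline
#'
#' Produces the three kinematic network inputs from raw joint-angle
#' recordings: the angle is low-pass filtered at `angle_cutoff_hz`, the
#' velocity is the filtered numerical derivative (cutoff
#' `velocity_cutoff_hz`), and the acceleration is the filtered derivative of
#' the velocity (cutoff `accel_cutoff_hz`). Defaults are 10/20/30 Hz. A
#' cutoff at or above Nyquist for the given rate is clamped to
#' 0.9 x Nyquist with a warning (at the typical 50 Hz marker rate the 30 Hz
#' acceleration default is unrealizable, so it is clamped to 22.5 Hz).
#'
#' For planar (single-axis) data each channel is treated as an independent
#' joint angle. If `euler_sequence` is given the input must have exactly 3
#' channels (an Euler-angle triple) and the raw angle derivatives are mapped
#' through the Euler-rate transformation before filtering.
#'
#' @param raw_angles [mcts] of joint angles in rad.
#' @param angle_cutoff_hz,velocity_cutoff_hz,accel_cutoff_hz filter cutoffs.
#' @param order Butterworth order.
#' @param euler_sequence optional axis triple for 3-channel Euler input.
#' @return a `kinematic_state`: list of `angle`, `velocity`, `acceleration`
#'   [mcts] objects sharing one rate and length.
#' @export
kinematic_pipeline <- function(raw_angles, angle_cutoff_hz = 10,
                               velocity_cutoff_hz = 20, accel_cutoff_hz = 30,
                               order = 4L, euler_sequence = NULL) {
  stopifnot(inherits(raw_angles, "mcts"))
  clamp_cut <- function(f) {
    nyq <- raw_angles$rate_hz / 2
    if (f >= nyq) {
      warning(sprintf("cutoff %g Hz >= Nyquist %g Hz; clamped to %g Hz",
                      f, nyq, 0.9 * nyq), call. = FALSE)
      0.9 * nyq
    } else f
  }
  angle <- lowpass_filter(raw_angles, clamp_cut(angle_cutoff_hz), order)
  dq <- differentiate(angle)
  if (!is.null(euler_sequence)) {
    if (n_channels(angle) != 3L)
      imnet_stop("Euler transformation needs exactly 3 angle channels",
                 "imnet_shape_error")
    w <- t(vapply(seq_len(n_samples(angle)), function(i)
      euler_rates_to_angular_velocity(angle$values[i, ], dq$values[i, ],
                                      euler_sequence), numeric(3)))
    dq <- mcts(w, angle$rate_hz, angle$channels, angle$start_s)
  }
  velocity <- lowpass_filter(dq, clamp_cut(velocity_cutoff_hz), order)
  acceleration <- lowpass_filter(differentiate(velocity),
                                 clamp_cut(accel_cutoff_hz), order)
  structure(list(angle = angle, velocity = velocity,
                 acceleration = acceleration),
            class = "kinematic_state")
}
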