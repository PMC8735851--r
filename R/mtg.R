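#' Muscle torque generator parameters
#'
#' The muscle torque generator (MTG) abstracts all muscles crossing a joint
#' into one torque actuator: `tau_h = tau_act * tau_a(theta) *
#' tau_v(theta_dot) + tau_p(theta)`. The three scaling functions are
#' parametric: a Gaussian torque-angle curve peaking at 1 at `theta_opt`, a
#' Hill-type torque-velocity curve normalized to 1 at zero velocity with a
#' bounded eccentric plateau at 1.5, and an exponential passive torque that
#' vanishes at `theta_ref`. Defaults place the optimum and reference in the
#' middle of a shoulder-elevation range of motion and keep the inversion
#' guard untouched for ordinary pick-and-place trajectories.
#'
#' @param theta_opt angle of peak active torque (rad).
#' @param width Gaussian width of the torque-angle curve (rad).
#' @param v_max maximum shortening (concentric) velocity (rad/s): active
#'   torque reaches 0 there.
#' @param shape dimensionless Hill shape factor (curvature of the
#'   torque-velocity relation; smaller = more curved).
#' @param k1,k2 passive torque magnitude (N m) and rate (1/rad).
#' @param theta_ref angle of zero passive torque (rad).
#' @param epsilon guard on the `tau_a * tau_v` denominator of the inversion.
#' @return an `mtg_params` list.
#' @export
mtg_params <- function(theta_opt = 1.2, width = 1.0, v_max = 12, shape = 0.25,
                       k1 = 1.5, k2 = 2.0, theta_ref = 1.2, epsilon = 1e-3) {
  if (width <= 0 || v_max <= 0 || shape <= 0 || epsilon <= 0 || k1 < 0)
    imnet_stop("width, v_max, shape and epsilon must be positive; k1 >= 0",
               "imnet_parameter_error")
  structure(list(theta_opt = theta_opt, width = width, v_max = v_max,
                 shape = shape, k1 = k1, k2 = k2, theta_ref = theta_ref,
                 epsilon = epsilon),
            class = "mtg_params")
}

#' MTG scaling functions
#'
#' `torque_angle_scale` is the Gaussian position scaling
#' `exp(-((theta - theta_opt)/width)^2)`, in (0, 1] with maximum 1 at
#' `theta_opt`. `torque_velocity_scale` is 1 at zero velocity, falls
#' hyperbolically to 0 at `v_max` for shortening (`theta_dot > 0`), is
#' clipped at 0 beyond, and rises C1-continuously toward a plateau of 1.5
#' for lengthening (`theta_dot < 0`); it is monotone non-increasing in
#' `theta_dot`. `passive_torque` is `k1 (exp(k2 (theta - theta_ref)) - 1)`
#' above `theta_ref`, mirrored (odd about `theta_ref`) below, hence
#' continuous, zero at `theta_ref` and strictly increasing.
#'
#' @param theta joint angle (rad); vectorized.
#' @param theta_dot joint velocity (rad/s); vectorized.
#' @param p an [mtg_params] object.
#' @return dimensionless scaling (or N m for `passive_torque`).
#' @export
torque_angle_scale <- function(theta, p) {
  exp(-((theta - p$theta_opt) / p$width)^2)
}

#' @rdname torque_angle_scale
#' @export
torque_velocity_scale <- function(theta_dot, p) {
  x <- theta_dot / p$v_max
  conc <- pmax(0, (1 - x) / (1 + x / p$shape))
  # eccentric branch: slope matched to the concentric branch at 0
  s <- 2 * (1 + 1 / p$shape) / p$v_max
  ecc <- 1.5 - 0.5 * exp(s * theta_dot)
  ifelse(theta_dot > 0, conc, ecc)
}

#' @rdname torque_angle_scale
#' @export
passive_torque <- function(theta, p) {
  d <- theta - p$theta_ref
  p$k1 * sign(d) * (exp(p$k2 * abs(d)) - 1)
}

#' Forward MTG model: activation torque to joint torque
#'
#' Evaluates `tau_h = tau_act * tau_a * tau_v + tau_p` sample-wise.
#'
#' @param tau_act activation torque (N m); vectorized.
#' @param theta,theta_dot joint state (rad, rad/s).
#' @param p an [mtg_params].
#' @return joint torque tau_h (N m).
#' @export
joint_torque_from_activation <- function(tau_act, theta, theta_dot, p) {
  tau_act * torque_angle_scale(theta, p) * torque_velocity_scale(theta_dot, p) +
    passive_torque(theta, p)
}

#' Invert the MTG model: joint torque to activation torque
#'
#' Algebraic inversion `tau_act = (tau_h - tau_p) / (tau_a * tau_v)`; this
#' is the computation that produces the activation-torque network input from
#' inverse-dynamics joint torque. The division is guarded: if
#' `|tau_a * tau_v|` falls below `p$epsilon` at any sample (e.g., shortening
#' at or beyond `v_max`), an error names the first offending sample instead
#' of silently amplifying noise into the network input.
#'
#' @inheritParams joint_torque_from_activation
#' @param tau_h joint torque (N m); vectorized.
#' @return activation torque (N m); exact round trip with
#'   [joint_torque_from_activation].
#' @export
activation_torque_from_joint_torque <- function(tau_h, theta, theta_dot, p) {
  den <- torque_angle_scale(theta, p) * torque_velocity_scale(theta_dot, p)
  bad <- which(abs(den) < p$epsilon)
  if (length(bad) > 0L)
    imnet_stop(sprintf(
      "MTG inversion guard tripped: |tau_a*tau_v| < %g at sample %d (of %d)",
      p$epsilon, bad[1L], length(bad)), "imnet_guard_error")
  (tau_h - passive_torque(theta, p)) / den
}
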