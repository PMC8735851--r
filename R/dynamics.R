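#' Body segment parameters
#'
#' @param length segment length (m).
#' @param mass segment mass (kg).
#' @param com_distance distance from the proximal joint to the segment
#'   center of mass (m); must not exceed `length`.
#' @param inertia_com moment of inertia about the center of mass (kg m^2).
#' @return a `segment_params` list.
#' @export
segment_params <- function(length, mass, com_distance, inertia_com) {
  vals <- c(length = length, mass = mass, com_distance = com_distance,
            inertia_com = inertia_com)
  if (any(!is.finite(vals)) || any(vals <= 0))
    imnet_stop("all segment parameters must be positive and finite",
               "imnet_parameter_error")
  if (com_distance > length)
    imnet_stop("com_distance must not exceed segment length",
               "imnet_parameter_error")
  structure(as.list(vals), class = "segment_params")
}

#' Planar two-link arm model
#'
#' Sagittal-plane reduction of the upper limb used for inverse dynamics:
#' shoulder elevation plus elbow flexion/extension, with the forearm and
#' hand lumped into one distal segment and an optional hand-held load as a
#' point mass at the distal endpoint. The default template is a mid-size
#' adult (`ref_mass` 75 kg, `ref_height` 1.75 m) with segment masses, lengths
#' and gyration radii in the range of standard anthropometric tables; use
#' [scale_segments] to adjust it to a subject.
#'
#' @param upper_arm,forearm_hand [segment_params] of the two links.
#' @param gravity gravitational acceleration (m/s^2).
#' @param hand_load_mass mass of a hand-held object (kg), lumped at the hand.
#' @param ref_mass,ref_height subject mass/height the template represents.
#' @return an `arm_model` list.
#' @export
arm_model <- function(upper_arm = segment_params(0.315, 2.1, 0.45 * 0.315,
                                                 2.1 * (0.31 * 0.315)^2),
                      forearm_hand = segment_params(0.45, 1.65, 0.41 * 0.45,
                                                    1.65 * (0.34 * 0.45)^2),
                      gravity = 9.81, hand_load_mass = 0,
                      ref_mass = 75, ref_height = 1.75) {
  if (gravity < 0 || hand_load_mass < 0)
    imnet_stop("gravity and hand_load_mass must be non-negative",
               "imnet_parameter_error")
  structure(list(upper_arm = upper_arm, forearm_hand = forearm_hand,
                 gravity = gravity, hand_load_mass = hand_load_mass,
                 ref_mass = ref_mass, ref_height = ref_height),
            class = "arm_model")
}

#' Scale an arm model to a subject's mass and height
#'
#' Segment masses scale linearly with total body mass, lengths (and center
#' of mass distances) with height, and inertias with mass x length^2, so all
#' template ratios are preserved. Scaling by the template's own reference
#' mass and height returns the template unchanged.
#'
#' @param total_mass,height subject anthropometrics (kg, m).
#' @param template an [arm_model] to scale.
#' @return a scaled `arm_model` whose reference anthropometrics are the
#'   subject's.
#' @export
scale_segments <- function(total_mass, height, template = arm_model()) {
  if (!is.finite(total_mass) || !is.finite(height) || total_mass <= 0 ||
      height <= 0)
    imnet_stop("mass and height must be positive", "imnet_parameter_error")
  km <- total_mass / template$ref_mass
  kl <- height / template$ref_height
  sc <- function(s) segment_params(s$length * kl, s$mass * km,
                                   s$com_distance * kl,
                                   s$inertia_com * km * kl^2)
  arm_model(sc(template$upper_arm), sc(template$forearm_hand),
            template$gravity, template$hand_load_mass,
            ref_mass = total_mass, ref_height = height)
}

# Closed-form planar two-link terms. q1 = shoulder elevation measured from
# the horizontal (+x) axis, q2 = elbow flexion relative to the upper arm;
# positive torque = counterclockwise = flexion/elevation. The hand load is a
# point mass at distance l2 from the elbow.
two_link_terms <- function(q, model) {
  s1 <- model$upper_arm; s2 <- model$forearm_hand
  m1 <- s1$mass; m2 <- s2$mass; mL <- model$hand_load_mass
  l1 <- s1$length; l2 <- s2$length
  c1 <- s1$com_distance; c2 <- s2$com_distance
  I1 <- s1$inertia_com; I2 <- s2$inertia_com
  g <- model$gravity
  cq2 <- cos(q[2L])
  B <- (m2 * l1 * c2 + mL * l1 * l2)
  M <- matrix(0, 2, 2)
  M[1, 1] <- I1 + m1 * c1^2 + I2 + m2 * (l1^2 + c2^2) + mL * (l1^2 + l2^2) +
    2 * B * cq2
  M[1, 2] <- M[2, 1] <- I2 + m2 * c2^2 + mL * l2^2 + B * cq2
  M[2, 2] <- I2 + m2 * c2^2 + mL * l2^2
  g1 <- g * ((m1 * c1 + (m2 + mL) * l1) * cos(q[1L]) +
               (m2 * c2 + mL * l2) * cos(q[1L] + q[2L]))
  g2 <- g * (m2 * c2 + mL * l2) * cos(q[1L] + q[2L])
  list(M = M, B = B, G = c(g1, g2))
}

#' Inverse dynamics of the planar two-link arm
#'
#' Solves the rigid-body equations of motion for the joint torque vector:
#' `Q(t) = M(q) qddot + C(q, qdot) qdot + G(q)`, evaluated sample-wise in
#' closed form for the shoulder-elbow chain, with any hand-held load lumped
#' at the distal endpoint. The shoulder component of Q is the human joint
#' torque used as a network input.
#'
#' @param kin a `kinematic_state` (from [kinematic_pipeline]) with exactly
#'   two channels ordered (shoulder, elbow).
#' @param model an [arm_model].
#' @return [mcts] with channels `shoulder_torque`, `elbow_torque` (N m).
#' @export
inverse_dynamics <- function(kin, model) {
  stopifnot(inherits(kin, "kinematic_state"), inherits(model, "arm_model"))
  if (n_channels(kin$angle) != 2L)
    imnet_stop("inverse_dynamics expects 2 joint channels (shoulder, elbow)",
               "imnet_shape_error")
  if (kin$angle$rate_hz != kin$velocity$rate_hz ||
      kin$angle$rate_hz != kin$acceleration$rate_hz)
    imnet_stop("kinematic channels must share one sample rate",
               "imnet_shape_error")
  n <- n_samples(kin$angle)
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    q <- kin$angle$values[i, ]
    qd <- kin$velocity$values[i, ]
    qdd <- kin$acceleration$values[i, ]
    tm <- two_link_terms(q, model)
    sq2 <- sin(q[2L])
    V <- c(-tm$B * sq2 * (2 * qd[1L] * qd[2L] + qd[2L]^2),
           tm$B * sq2 * qd[1L]^2)
    out[i, ] <- as.numeric(tm$M %*% qdd) + V + tm$G
  }
  mcts(out, kin$angle$rate_hz, c("shoulder_torque", "elbow_torque"),
       kin$angle$start_s)
}

#' Mass matrix of the planar two-link arm at a configuration
#'
#' @param q numeric pair of joint angles (rad).
#' @param model an [arm_model].
#' @return symmetric positive-definite 2x2 matrix (kg m^2).
#' @export
mass_matrix <- function(q, model) two_link_terms(q, model)$M

#' Mechanical energy of the planar two-link arm
#'
#' Kinetic plus gravitational potential energy; used for work-energy
#' consistency checks of [inverse_dynamics].
#'
#' @param q,qd joint angles (rad) and velocities (rad/s), numeric pairs.
#' @param model an [arm_model].
#' @return energy in J (potential zero level at shoulder height).
#' @export
arm_energy <- function(q, qd, model) {
  tm <- two_link_terms(q, model)
  s1 <- model$upper_arm; s2 <- model$forearm_hand
  mL <- model$hand_load_mass
  kin <- 0.5 * as.numeric(t(qd) %*% tm$M %*% qd)
  pot <- model$gravity *
    ((s1$mass * s1$com_distance + (s2$mass + mL) * s1$length) * sin(q[1L]) +
       (s2$mass * s2$com_distance + mL * s2$length) * sin(q[1L] + q[2L]))
  kin + pot
}
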