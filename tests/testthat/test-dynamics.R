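test_that("inverse dynamics matches hand-derived static and zero cases", {
  am <- arm_model(hand_load_mass = 0.5)
  zero_g <- arm_model(gravity = 0, hand_load_mass = 0.5)
  ch <- c("shoulder", "elbow")
  static <- function(q) structure(
    list(angle = mcts(matrix(q, 1), 50, ch),
         velocity = mcts(matrix(0, 1, 2), 50, ch),
         acceleration = mcts(matrix(0, 1, 2), 50, ch)),
    class = "kinematic_state")

  # no gravity, no motion: both torques vanish
  expect_equal(inverse_dynamics(static(c(0.7, 0.9)), zero_g)$values,
               matrix(0, 1, 2), ignore_attr = TRUE)

  # static hold: elbow torque is the gravity moment of the distal segment
  # plus load about the elbow (independent hand derivation)
  q <- c(0.8, 0.4)
  Q <- inverse_dynamics(static(q), am)$values
  s2 <- am$forearm_hand
  expect_equal(unname(Q[1, 2]),
               (s2$mass * s2$com_distance + 0.5 * s2$length) * am$gravity *
                 cos(sum(q)),
               tolerance = 1e-12)
})

test_that("inverse dynamics agrees with the finite-difference Lagrangian oracle", {
  am <- arm_model(hand_load_mass = 0.5)
  f <- c(0.7, 0.5); a <- c(0.4, 0.3); q0 <- c(0.9, 0.8)
  state_fn <- function(tt) list(
    q = c(q0[1] + a[1] * sin(2 * pi * f[1] * tt),
          q0[2] + a[2] * cos(2 * pi * f[2] * tt)),
    qd = c(a[1] * 2 * pi * f[1] * cos(2 * pi * f[1] * tt),
           -a[2] * 2 * pi * f[2] * sin(2 * pi * f[2] * tt)),
    qdd = c(-a[1] * (2 * pi * f[1])^2 * sin(2 * pi * f[1] * tt),
            -a[2] * (2 * pi * f[2])^2 * cos(2 * pi * f[2] * tt)))
  ch <- c("shoulder", "elbow")
  for (tt in c(0.31, 0.77, 1.24)) {
    st <- state_fn(tt)
    kin <- structure(list(angle = mcts(matrix(st$q, 1), 50, ch),
                          velocity = mcts(matrix(st$qd, 1), 50, ch),
                          acceleration = mcts(matrix(st$qdd, 1), 50, ch)),
                     class = "kinematic_state")
    Q <- inverse_dynamics(kin, am)$values
    for (j in 1:2) {
      oq <- oracle_torque(state_fn, tt, am, j)
      expect_equal(unname(Q[1, j]), oq, tolerance = 1e-6)
    }
  }
})

test_that("work-energy theorem holds along a smooth trajectory", {
  am <- arm_model(hand_load_mass = 0.5)
  kin <- analytic_kin(rate_hz = 500, duration_s = 2)
  Q <- inverse_dynamics(kin, am)$values
  P <- rowSums(Q * kin$velocity$values)
  W <- sum((P[-1] + P[-length(P)]) / 2) / 500
  E <- vapply(seq_len(n_samples(kin$angle)), function(i)
    arm_energy(kin$angle$values[i, ], kin$velocity$values[i, ], am),
    numeric(1))
  scale <- max(E) - min(E)
  expect_lt(abs(W - (E[length(E)] - E[1])) / scale, 0.005)
})

test_that("mass matrix is symmetric positive definite everywhere", {
  am <- arm_model(hand_load_mass = 1)
  set.seed(5)
  for (i in 1:1000) {
    q <- stats::runif(2, -pi, pi)
    M <- mass_matrix(q, am)
    expect_identical(M[1, 2], M[2, 1])
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("inverse dynamics is affine in acceleration at fixed state", {
  am <- arm_model()
  ch <- c("shoulder", "elbow")
  kin_with <- function(qdd) structure(
    list(angle = mcts(matrix(c(0.6, 1.1), 1), 50, ch),
         velocity = mcts(matrix(c(0.4, -0.2), 1), 50, ch),
         acceleration = mcts(matrix(qdd, 1), 50, ch)),
    class = "kinematic_state")
  Q <- function(qdd) inverse_dynamics(kin_with(qdd), am)$values[1, ]
  a <- 0.7; b <- -1.3
  q1 <- c(1.5, -0.5); q2 <- c(-0.3, 2.1)
  lhs <- Q(a * q1 + b * q2)
  rhs <- a * Q(q1) + b * Q(q2) - (a + b - 1) * Q(c(0, 0))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("segment scaling preserves template ratios", {
  tmpl <- arm_model()
  same <- scale_segments(tmpl$ref_mass, tmpl$ref_height, tmpl)
  expect_equal(same$upper_arm, tmpl$upper_arm)

  dbl <- scale_segments(2 * tmpl$ref_mass, tmpl$ref_height, tmpl)
  expect_equal(dbl$upper_arm$mass, 2 * tmpl$upper_arm$mass)
  expect_equal(dbl$upper_arm$inertia_com, 2 * tmpl$upper_arm$inertia_com)
  expect_equal(dbl$upper_arm$length, tmpl$upper_arm$length)

  any_s <- scale_segments(61, 1.55, tmpl)
  expect_equal(any_s$upper_arm$mass / any_s$forearm_hand$mass,
               tmpl$upper_arm$mass / tmpl$forearm_hand$mass)
  expect_error(scale_segments(-1, 1.7, tmpl), class = "imnet_parameter_error")
})
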