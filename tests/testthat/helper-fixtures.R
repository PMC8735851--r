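# Shared fixtures, all generated in code.

sine_ts <- function(freq_hz, rate_hz, duration_s = 2, amp = 1, phase = 0) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  mcts(amp * sin(2 * pi * freq_hz * t + phase), rate_hz, "x")
}

# smooth band-limited random signal (for property tests over trajectories)
smooth_signal <- function(n, rate_hz = 50, cutoff_hz = 2, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n + 200)
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  y[101:(100 + n)]
}

# two-joint kinematic state built from analytic sinusoids (exact derivatives)
analytic_kin <- function(rate_hz = 200, duration_s = 2,
                         f = c(0.7, 0.5), a = c(0.4, 0.3),
                         q0 = c(0.9, 0.8)) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  q <- cbind(q0[1] + a[1] * sin(2 * pi * f[1] * t),
             q0[2] + a[2] * cos(2 * pi * f[2] * t))
  qd <- cbind(a[1] * 2 * pi * f[1] * cos(2 * pi * f[1] * t),
              -a[2] * 2 * pi * f[2] * sin(2 * pi * f[2] * t))
  qdd <- cbind(-a[1] * (2 * pi * f[1])^2 * sin(2 * pi * f[1] * t),
               -a[2] * (2 * pi * f[2])^2 * cos(2 * pi * f[2] * t))
  ch <- c("shoulder", "elbow")
  structure(list(angle = mcts(q, rate_hz, ch),
                 velocity = mcts(qd, rate_hz, ch),
                 acceleration = mcts(qdd, rate_hz, ch)),
            class = "kinematic_state")
}

# independent Lagrangian of the two-link arm from first principles
# (positions/velocities of the mass points), used as a dynamics oracle
lagrangian_oracle <- function(q, qd, model) {
  s1 <- model$upper_arm; s2 <- model$forearm_hand
  mL <- model$hand_load_mass; g <- model$gravity
  c1 <- cos(q[1]); s1a <- sin(q[1])
  c12 <- cos(q[1] + q[2]); s12 <- sin(q[1] + q[2])
  v1 <- s1$com_distance * c(-s1a, c1) * qd[1]
  ve <- s1$length * c(-s1a, c1) * qd[1]
  v2 <- ve + s2$com_distance * c(-s12, c12) * (qd[1] + qd[2])
  vh <- ve + s2$length * c(-s12, c12) * (qd[1] + qd[2])
  Tk <- 0.5 * s1$mass * sum(v1^2) + 0.5 * s1$inertia_com * qd[1]^2 +
    0.5 * s2$mass * sum(v2^2) + 0.5 * s2$inertia_com * (qd[1] + qd[2])^2 +
    0.5 * mL * sum(vh^2)
  V <- g * (s1$mass * s1$com_distance * s1a +
              s2$mass * (s1$length * s1a + s2$com_distance * s12) +
              mL * (s1$length * s1a + s2$length * s12))
  Tk - V
}

# generalized forces from the Lagrangian oracle along an analytic
# trajectory: d/dt dL/dqd - dL/dq, all derivatives by central differences
# on analytically evaluated states (dt decoupled from the sample grid)
oracle_torque <- function(state_fn, t, model, j, h = 1e-6, dt = 1e-4) {
  dLdqd_at <- function(tt) {
    st <- state_fn(tt)
    e <- c(0, 0); e[j] <- h
    (lagrangian_oracle(st$q, st$qd + e, model) -
       lagrangian_oracle(st$q, st$qd - e, model)) / (2 * h)
  }
  ddt <- (dLdqd_at(t + dt) - dLdqd_at(t - dt)) / (2 * dt)
  st <- state_fn(t)
  e <- c(0, 0); e[j] <- h
  dLdq <- (lagrangian_oracle(st$q + e, st$qd, model) -
             lagrangian_oracle(st$q - e, st$qd, model)) / (2 * h)
  ddt - dLdq
}

# sin/cos regression amplitude of a frequency component
tone_amplitude <- function(x, freq_hz, rate_hz) {
  t <- (seq_along(x) - 1) / rate_hz
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * freq_hz * t) +
                                cos(2 * pi * freq_hz * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# tiny multi-subject cohort with targets generated by a known smooth map of
# the inputs (subset `active`), for selection/ranking tests
planted_cohort <- function(n_subjects = 2, n = 400, n_inputs = 5,
                           active = c(1, 2), noise_sd = 0.02, seed = 1) {
  lapply(seq_len(n_subjects), function(s) {
    set.seed(seed * 1000 + s)
    U <- vapply(seq_len(n_inputs), function(j)
      smooth_signal(n, 50, 2, seed = seed * 100 + 10 * s + j), numeric(n))
    colnames(U) <- paste0("in", seq_len(n_inputs))
    z <- rowSums(U[, active, drop = FALSE] %*%
                   diag(seq_along(active) + 0.5, length(active)))
    y <- 1 / (1 + exp(-2 * z)) + noise_sd * stats::rnorm(n)
    y <- pmin(pmax(y, 0), 1)
    list(id = sprintf("P%02d", s),
         trials = list(list(inputs = U, targets = matrix(y, ncol = 1,
                                                         dimnames = list(NULL, "y")))))
  })
}

# small teacher-mode cohort for training tests
tiny_teacher_cohort <- function(n_subjects = 5, duration_s = 6, seed = 7) {
  spec <- cohort_spec(n_subjects = n_subjects, trials_per_subject = 1,
                      trial_duration_s = duration_s, seed = seed)
  generate_cohort(spec, mode = "narx_teacher")
}
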