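#' Synthetic cohort specification
#'
#' Describes a multi-subject planar pick-and-place cohort with the
#' statistical structure the pipeline assumes: 17 subjects performing 12
#' trials each of smooth cyclic shoulder-elevation motion, anthropometrics
#' drawn from a population with mass 72.25 +/- 29.85 kg and height
#' 1.66 +/- 0.16 m (truncated at +/- 2 SD), eleven named shoulder-girdle
#' EMG sites, and raw EMG synthesized at 1500 Hz.
#'
#' @param n_subjects number of subjects (default 17).
#' @param trials_per_subject trials per subject (default 12).
#' @param trial_duration_s duration of one trial (default 20 s).
#' @param cycle_rate_hz pick-and-place cadence (default 0.4 Hz, one
#'   lift-lower cycle every 2.5 s).
#' @param mass_mean,mass_sd,height_mean,height_sd anthropometric population.
#' @param emg_channels muscle codes of the EMG sites.
#' @param emg_snr_db raw-EMG signal-to-additive-noise ratio (default 15 dB).
#' @param kinematic_noise_sd white measurement noise added to the raw joint
#'   angles before the kinematic pipeline (rad; default 0.002).
#' @param rate_hz kinematic sample rate (default 50).
#' @param emg_rate_hz raw EMG sample rate (default 1500).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 17L, trials_per_subject = 12L,
                        trial_duration_s = 20, cycle_rate_hz = 0.4,
                        mass_mean = 72.25, mass_sd = 29.85,
                        height_mean = 1.66, height_sd = 0.16,
                        emg_channels = c("SERR", "MDEL", "SUPR", "INFR",
                                         "PDEL", "PECC", "LATS", "ADEL",
                                         "MTRA", "UTRA", "LTRA"),
                        emg_snr_db = 15, kinematic_noise_sd = 0.002,
                        rate_hz = 50, emg_rate_hz = 1500, seed = 1L) {
  if (n_subjects < 1L || trials_per_subject < 1L || trial_duration_s <= 0)
    imnet_stop("counts and durations must be positive", "imnet_parameter_error")
  if (!is.finite(emg_snr_db))
    imnet_stop("SNR must be finite", "imnet_parameter_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 trial_duration_s = trial_duration_s,
                 cycle_rate_hz = cycle_rate_hz, mass_mean = mass_mean,
                 mass_sd = mass_sd, height_mean = height_mean,
                 height_sd = height_sd, emg_channels = emg_channels,
                 emg_snr_db = emg_snr_db,
                 kinematic_noise_sd = kinematic_noise_sd, rate_hz = rate_hz,
                 emg_rate_hz = emg_rate_hz, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Minimum-jerk trajectory through waypoints
#'
#' Piecewise quintic (minimum-jerk) segments with zero velocity and
#' acceleration at every waypoint, C2-continuous - the standard smooth
#' stand-in for point-to-point reaching motion.
#'
#' @param waypoints numeric vector of positions (e.g. joint angles, rad).
#' @param durations segment durations in seconds (length =
#'   `length(waypoints) - 1`).
#' @param rate_hz output sample rate.
#' @return single-channel [mcts] of the trajectory.
#' @export
minimum_jerk_trajectory <- function(waypoints, durations, rate_hz = 50) {
  if (length(waypoints) < 2L)
    imnet_stop("need at least 2 waypoints", "imnet_parameter_error")
  if (length(durations) != length(waypoints) - 1L || any(durations <= 0))
    imnet_stop("durations must be positive, one per segment",
               "imnet_parameter_error")
  total <- sum(durations)
  t <- seq(0, total, by = 1 / rate_hz)
  starts <- cumsum(c(0, durations))
  seg <- pmin(findInterval(t, starts, rightmost.closed = TRUE),
              length(durations))
  s <- (t - starts[seg]) / durations[seg]
  # minimum-jerk scalar profile: 10 s^3 - 15 s^4 + 6 s^5
  blend <- 10 * s^3 - 15 * s^4 + 6 * s^5
  x <- waypoints[seg] + (waypoints[seg + 1L] - waypoints[seg]) * blend
  mcts(matrix(x, ncol = 1L), rate_hz, "angle")
}

# cyclic pick-and-place waypoint pattern for one trial
pick_place_waypoints <- function(duration_s, cycle_rate_hz, lo, hi, rng_jitter) {
  n_cycles <- max(1L, floor(duration_s * cycle_rate_hz))
  wp <- c(lo, rep(c(hi, lo), n_cycles))
  wp <- wp + rng_jitter * stats::rnorm(length(wp))
  seg <- rep(duration_s / (length(wp) - 1L), length(wp) - 1L)
  list(waypoints = wp, durations = seg)
}

# First-order low-pass (activation-like lag), time constant tau_s.
first_order_lag <- function(x, rate_hz, tau_s) {
  a <- exp(-1 / (rate_hz * tau_s))
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive",
                           init = x[1]))
}

synth_raw_emg <- function(activation, rate_hz, emg_rate_hz, snr_db,
                          duration_s) {
  n_hi <- round(duration_s * emg_rate_hz) + 1L
  t_hi <- (seq_len(n_hi) - 1L) / emg_rate_hz
  t_lo <- (seq_along(activation) - 1L) / rate_hz
  act_hi <- stats::approx(t_lo, activation, xout = pmin(t_hi, max(t_lo)),
                          rule = 2)$y
  carrier <- stats::rnorm(n_hi)
  bf <- signal::butter(4, c(20, 450) / (emg_rate_hz / 2), type = "pass")
  carrier <- signal::filtfilt(bf, carrier)
  carrier <- carrier / stats::sd(carrier)
  sig <- carrier * act_hi
  sig_rms <- sqrt(mean(sig^2))
  if (sig_rms == 0) sig_rms <- 1
  mains <- 0.2 * sig_rms * sqrt(2) * sin(2 * pi * 60 * t_hi)
  noise_rms <- sig_rms / (10^(snr_db / 20))
  sig + mains + noise_rms * stats::rnorm(n_hi)
}

#' Generate one synthetic subject
#'
#' Two generation modes share the same biomechanical front end: the subject
#' gets anthropometrics sampled from the cohort population, a scaled arm
#' model, and per-trial minimum-jerk shoulder/elbow trajectories. Joint
#' torque comes from the package's own inverse dynamics and activation
#' torque from the MTG inversion, so the five input channels are mutually
#' consistent by construction.
#'
#' In `mechanistic` mode the true muscle activations are rectified signed
#' shares of the activation torque passed through a first-order lag
#' (agonist/antagonist split plus a small co-contraction floor), scaled by
#' per-subject per-muscle gains; raw EMG is synthesized at 1500 Hz as
#' band-limited Gaussian carrier amplitude-modulated by the true
#' activation, plus 60 Hz interference and white noise at the spec SNR. In
#' `narx_teacher` mode the targets are produced by running a fixed,
#' randomly initialized reference NARX network closed-loop on the
#' standardized biomechanical inputs, which guarantees the input-output
#' mapping lies inside the model class (used for recovery studies).
#'
#' @param spec a [cohort_spec].
#' @param subject_index 1-based subject index (drives the derived seed).
#' @param mode `"mechanistic"` or `"narx_teacher"`.
#' @param teacher optional `narx_model` shared by the cohort in
#'   `narx_teacher` mode; one is created from the spec seed if missing.
#' @param include_raw_emg generate the 1500 Hz raw EMG channels
#'   (mechanistic mode only; the dominant memory cost).
#' @return list with `dataset` (subject dataset: `id`, `anthropometrics`,
#'   `trials` of `inputs`/`targets` [mcts]) and `truth` (per-trial true
#'   activations, raw EMG if requested, and the teacher model in
#'   `narx_teacher` mode).
#' @export
generate_subject <- function(spec, subject_index,
                             mode = c("mechanistic", "narx_teacher"),
                             teacher = NULL, include_raw_emg = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  sseed <- derive_seed(spec$seed, subject_index, 10L)
  if (mode == "narx_teacher" && is.null(teacher))
    teacher <- make_teacher(spec)
  with_seed(sseed, {
    mass <- pmin(pmax(stats::rnorm(1, spec$mass_mean, spec$mass_sd),
                      spec$mass_mean - 2 * spec$mass_sd),
                 spec$mass_mean + 2 * spec$mass_sd)
    mass <- max(mass, 30)
    height <- pmin(pmax(stats::rnorm(1, spec$height_mean, spec$height_sd),
                        spec$height_mean - 2 * spec$height_sd),
                   spec$height_mean + 2 * spec$height_sd)
    model <- scale_segments(mass, height, arm_model(hand_load_mass = 0.5))
    mtg <- mtg_params()
    n_m <- length(spec$emg_channels)
    # fixed per-subject muscle gains and agonist/antagonist assignment
    gains <- stats::runif(n_m, 0.6, 1.4)
    agonist <- rep_len(c(TRUE, FALSE), n_m)
    trials <- vector("list", spec$trials_per_subject)
    truth <- vector("list", spec$trials_per_subject)
    for (k in seq_len(spec$trials_per_subject)) {
      sh <- pick_place_waypoints(spec$trial_duration_s, spec$cycle_rate_hz,
                                 lo = 0.45, hi = 1.5, rng_jitter = 0.03)
      el <- pick_place_waypoints(spec$trial_duration_s, spec$cycle_rate_hz,
                                 lo = 1.15, hi = 0.55, rng_jitter = 0.03)
      th_s <- minimum_jerk_trajectory(sh$waypoints, sh$durations, spec$rate_hz)
      th_e <- minimum_jerk_trajectory(el$waypoints, el$durations, spec$rate_hz)
      n <- min(n_samples(th_s), n_samples(th_e))
      raw <- mcts(cbind(shoulder = th_s$values[seq_len(n), 1L],
                        elbow = th_e$values[seq_len(n), 1L]) +
                    spec$kinematic_noise_sd * stats::rnorm(2L * n),
                  spec$rate_hz, c("shoulder", "elbow"))
      kin <- suppressWarnings(kinematic_pipeline(raw))
      tau <- inverse_dynamics(kin, model)
      tau_act <- activation_torque_from_joint_torque(
        tau$values[, "shoulder_torque"], kin$angle$values[, "shoulder"],
        kin$velocity$values[, "shoulder"], mtg)
      inputs <- mcts(cbind(angle = kin$angle$values[, "shoulder"],
                           velocity = kin$velocity$values[, "shoulder"],
                           acceleration = kin$acceleration$values[, "shoulder"],
                           joint_torque = tau$values[, "shoulder_torque"],
                           activation_torque = tau_act),
                     spec$rate_hz)
      if (mode == "mechanistic") {
        pos <- pmax(tau_act, 0); neg <- pmax(-tau_act, 0)
        scale_t <- stats::quantile(abs(tau_act), 0.95) + 1e-9
        act <- vapply(seq_len(n_m), function(j) {
          drive <- if (agonist[j]) pos else neg
          a <- gains[j] * drive / scale_t + 0.05
          a <- first_order_lag(a, spec$rate_hz, 0.04)
          pmin(pmax(a, 0), 1)
        }, numeric(n))
        colnames(act) <- spec$emg_channels
        targets <- mcts(act, spec$rate_hz, spec$emg_channels)
        raw_emg <- NULL
        if (include_raw_emg) {
          emg <- vapply(seq_len(n_m), function(j)
            synth_raw_emg(act[, j], spec$rate_hz, spec$emg_rate_hz,
                          spec$emg_snr_db, (n - 1L) / spec$rate_hz),
            numeric(round((n - 1L) / spec$rate_hz * spec$emg_rate_hz) + 1L))
          colnames(emg) <- spec$emg_channels
          raw_emg <- mcts(emg, spec$emg_rate_hz, spec$emg_channels)
        }
        trials[[k]] <- list(inputs = inputs, targets = targets)
        truth[[k]] <- list(activation = targets, raw_emg = raw_emg)
      } else {
        u <- sweep(sweep(inputs$values, 2L, attr(teacher, "u_center"), "-"),
                   2L, attr(teacher, "u_scale"), "/")
        y <- forward_closed_loop(teacher, u)
        w <- narx_warmup(teacher$config)
        # prepend the zero warm-up so targets align with the inputs
        y_full <- rbind(matrix(0, w, ncol(y)), y)
        colnames(y_full) <- spec$emg_channels[seq_len(ncol(y))]
        targets <- mcts(y_full, spec$rate_hz)
        trials[[k]] <- list(inputs = inputs, targets = targets)
        truth[[k]] <- list(activation = targets)
      }
    }
    list(dataset = list(id = sprintf("S%02d", subject_index),
                        anthropometrics = c(mass = mass, height = height),
                        trials = trials),
         truth = list(trials = truth,
                      teacher = if (mode == "narx_teacher") teacher))
  })
}

# Reference teacher network for narx_teacher mode: fixed config
# (1 hidden layer, 10 nodes, taps 3/5), weights scaled for a non-degenerate
# output range, input standardization advertised via attributes (the
# generator standardizes with typical pick-and-place signal scales).
make_teacher <- function(spec) {
  n_out <- min(6L, length(spec$emg_channels))
  cfg <- narx_config(5L, n_out, n_l = 1L, n_n = 10L, n_u = 3L, n_y = 5L)
  teacher <- init_model(cfg, derive_seed(spec$seed, 0L, 20L))
  teacher$IW <- teacher$IW * 6
  teacher$OW <- teacher$OW * 3
  teacher$b2 <- with_seed(derive_seed(spec$seed, 1L, 20L),
                          stats::runif(n_out, 0.3, 0.6))
  # nominal channel scales of the planar task (angle rad, velocity rad/s,
  # acceleration rad/s^2, torques N m)
  attr(teacher, "u_center") <- c(1.0, 0, 0, 10, 15)
  attr(teacher, "u_scale") <- c(0.5, 1.5, 6, 12, 18)
  teacher
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec].
#' @param mode see [generate_subject].
#' @param include_raw_emg see [generate_subject].
#' @return list with `subjects` (list of subject datasets), `truth`
#'   (per-subject ground truth), and `spec`.
#' @export
generate_cohort <- function(spec, mode = c("mechanistic", "narx_teacher"),
                            include_raw_emg = TRUE) {
  mode <- match.arg(mode)
  teacher <- if (mode == "narx_teacher") make_teacher(spec)
  out <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject(spec, i, mode, teacher = teacher,
                     include_raw_emg = include_raw_emg))
  list(subjects = lapply(out, `[[`, "dataset"),
       truth = lapply(out, `[[`, "truth"), spec = spec,
       teacher = teacher)
}
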