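# synthetic amplitude-modulated EMG with known ground-truth envelope
am_emg_fixture <- function(duration_s = 6, rate_hz = 1500, seed = 21,
                           mains_gain = 2) {
  set.seed(seed)
  n <- duration_s * rate_hz + 1
  t <- (seq_len(n) - 1) / rate_hz
  carrier <- stats::rnorm(n)
  bf <- signal::butter(4, c(80, 350) / (rate_hz / 2), type = "pass")
  carrier <- signal::filtfilt(bf, carrier)
  carrier <- carrier / stats::sd(carrier)
  envelope <- 0.5 * (1 - cos(2 * pi * 0.5 * t))  # raised cosine, 0.5 Hz
  signal_part <- carrier * envelope
  mains <- mains_gain * sqrt(mean(signal_part^2)) * sqrt(2) *
    sin(2 * pi * 60 * t)
  list(raw = mcts(signal_part + mains, rate_hz, "MDEL"),
       envelope = envelope, t = t, rate_hz = rate_hz)
}

test_that("shaping function fixes endpoints and bends as specified", {
  for (A in c(-3, -1, 0.5, 3)) {
    expect_equal(shaping_function(0, A), 0)
    expect_equal(shaping_function(1, A), 1)
    u <- seq(0, 1, by = 0.01)
    expect_true(all(diff(shaping_function(u, A)) > 0))
  }
  expect_identical(shaping_function(c(0, 0.3, 1), 0), c(0, 0.3, 1))
  expect_equal(shaping_function(0.5, -3), (exp(-1.5) - 1) / (exp(-3) - 1),
               tolerance = 1e-12)
  expect_equal(shaping_function(0.5, -3), 0.8175745, tolerance = 1e-6)
  expect_error(shaping_function(1.2, -1), class = "imnet_domain_error")
})

test_that("seven-step chain recovers a known AM envelope and notches mains", {
  fx <- am_emg_fixture()
  out <- filter_emg_chain(fx$raw, emg_filter_settings(shape_factor = 0),
                          return_stages = TRUE)
  env <- out$envelope
  expect_equal(env$rate_hz, 50)
  expect_equal(n_samples(env), round(6 * 50) + 1, tolerance = 1)
  expect_true(all(env$values >= 0 & env$values <= 1))
  expect_equal(max(env$values), 1)

  # correlation with the true modulation, edge transients trimmed
  trim <- round(0.25 * 50)
  idx <- (trim + 1):(n_samples(env) - trim)
  truth <- stats::approx(fx$t, fx$envelope, xout = time_points(env))$y
  expect_gt(stats::cor(env$values[idx, 1], truth[idx]), 0.95)

  # 60 Hz interferer attenuated by more than 20 dB at the band-stop stage
  a_in <- tone_amplitude(fx$raw$values[, 1], 60, fx$rate_hz)
  a_out <- tone_amplitude(out$stages$bandstopped[, 1], 60, fx$rate_hz)
  expect_lt(20 * log10(a_out / a_in), -20)
})

test_that("constant-envelope input yields a near-constant output envelope", {
  # carrier band 20-450 Hz as in the synthetic EMG generator: the residual
  # demodulation ripple scales as sqrt(envelope bandwidth / carrier
  # bandwidth), so the full-width carrier is the relevant regime
  set.seed(33)
  rate <- 1500; n <- 5 * rate + 1
  carrier <- stats::rnorm(n)
  bf <- signal::butter(4, c(20, 450) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, carrier)
  out <- filter_emg_chain(mcts(x, rate, "SERR"),
                          emg_filter_settings(shape_factor = 0))
  trim <- round(0.5 * 50)
  v <- out$values[(trim + 1):(n_samples(out) - trim), 1]
  expect_lt(stats::sd(v) / mean(v), 0.10)
})

test_that("chained output equals the steps applied one by one", {
  fx <- am_emg_fixture(duration_s = 3, seed = 4)
  st <- emg_filter_settings()
  res <- filter_emg_chain(fx$raw, st, return_stages = TRUE)
  nyq <- fx$rate_hz / 2
  zp <- asNamespace("imnet")$zp_filter
  bp <- signal::butter(4, st$bandpass / nyq, type = "pass")
  bs <- signal::butter(4, st$bandstop / nyq, type = "stop")
  lp <- signal::butter(4, st$envelope_lowpass_hz / nyq, type = "low")
  x <- zp(bp, fx$raw$values[, 1],
          min(st$bandpass[1], diff(st$bandpass)) / nyq)
  x <- zp(bs, x, diff(st$bandstop) / nyq)
  x <- abs(x)
  x <- pmax(zp(lp, x, st$envelope_lowpass_hz / nyq), 0)
  x <- x / max(x)
  t_in <- fx$t
  t_out <- seq(0, t_in[length(t_in)], by = 1 / 50)
  y <- stats::spline(t_in, x, xout = t_out, method = "fmm")$y
  y <- pmin(pmax(y, 0), 1); y <- y / max(y)
  y <- shaping_function(y, st$shape_factor)
  expect_equal(as.numeric(res$envelope$values), y, tolerance = 1e-10)
})

test_that("normalization is idempotent on an already-processed envelope", {
  fx <- am_emg_fixture(duration_s = 4, seed = 8)
  st <- emg_filter_settings(shape_factor = 0)
  once <- filter_emg_chain(fx$raw, st)
  # feed the 50 Hz envelope back through envelope smoothing + normalization
  st2 <- emg_filter_settings(shape_factor = 0, preset = "three_step",
                             highpass_hz = 0.01, lowpass_hz = 7)
  again <- filter_emg_chain(once, st2)
  expect_equal(max(again$values), 1)
})

test_that("three-step preset high-pass strongly attenuates low frequencies", {
  s <- sine_ts(10, 1500, duration_s = 4)
  st <- emg_filter_settings(preset = "three_step")
  nyq <- 750
  hp <- signal::butter(4, st$highpass_hz / nyq, type = "high")
  y <- signal::filtfilt(hp, s$values[, 1])
  mid <- 2000:4000
  atten <- 20 * log10(max(abs(y[mid])) / 1)
  expect_lt(atten, -30)
})

test_that("degenerate EMG inputs are rejected with informative errors", {
  z <- mcts(matrix(0, 3000, 2), 1500, c("a", "b"))
  expect_error(filter_emg_chain(z), class = "imnet_normalization_error")
  short <- mcts(matrix(rnorm(300), ncol = 1), 1500, "a")
  expect_error(filter_emg_chain(short), class = "imnet_data_error")
})
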