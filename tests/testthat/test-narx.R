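test_that("parameter count matches hand enumeration and scales per layer", {
  # 5 inputs, 1 tap, no feedback, 20 nodes: 20*5 + 20 + 6*20 + 6
  cfg <- narx_config(5, 6, n_l = 1, n_n = 20, n_u = 1, n_y = 0)
  expect_identical(count_parameters(cfg), 246L)
  cfg2 <- narx_config(5, 6, n_l = 2, n_n = 20, n_u = 1, n_y = 0)
  expect_equal(count_parameters(cfg2), 246 + 20^2 + 20)
  expect_error(narx_config(5, 6, n_u = 0), class = "imnet_parameter_error")
})

test_that("delay-window durations follow the tap counts", {
  expect_equal(delay_window_duration(narx_config(5, 6, n_u = 1, n_y = 1), 50),
               c(input_s = 0.02, feedback_s = 0.02))
  cfg <- narx_config(5, 6, n_u = 4, n_y = 6)
  d50 <- delay_window_duration(cfg, 50)
  d25 <- delay_window_duration(cfg, 25)
  expect_equal(d25, 2 * d50, ignore_attr = TRUE)
})

test_that("initialization is deterministic, bounded, and seed-sensitive", {
  cfg <- narx_config(3, 2, n_n = 8, n_u = 2, n_y = 3)
  m1 <- init_model(cfg, 123)
  m2 <- init_model(cfg, 123)
  m3 <- init_model(cfg, 124)
  expect_identical(m1$IW, m2$IW)
  expect_identical(m1$OW, m2$OW)
  expect_false(identical(m1$IW, m3$IW))
  expect_true(all(abs(m1$IW) <= 0.5))
  expect_true(all(abs(m1$OW) <= 0.5))
})

test_that("open-loop forward pass matches hand computation", {
  # zero weights: saturate(0) = 0 everywhere
  cfg <- narx_config(2, 1, n_n = 4, n_u = 2, n_y = 2)
  m <- init_model(cfg, 1)
  m$IW[] <- 0; m$OW[] <- 0; m$b2[] <- 0
  u <- matrix(rnorm(40), 20, 2)
  y <- matrix(runif(20), 20, 1)
  p <- forward_open_loop(m, u, y)
  expect_equal(nrow(p), 20 - max(cfg$n_u - 1, cfg$n_y))
  expect_true(all(p == 0))

  # hand-sized net: 1 input, 1 output, 1 node, taps (1,1), logistic hidden,
  # IW = [1, 0] so prediction = saturate(sigmoid(u(t)))
  cfg1 <- narx_config(1, 1, n_n = 1, n_u = 1, n_y = 1)
  m1 <- init_model(cfg1, 1)
  m1$IW <- matrix(c(1, 0), 1, 2); m1$b1 <- 0
  m1$OW <- matrix(1, 1, 1); m1$b2 <- 0
  u1 <- matrix(c(0.7, 0, -0.4, 2), 4, 1)
  y1 <- matrix(0.5, 4, 1)
  p1 <- forward_open_loop(m1, u1, y1)
  expect_equal(as.numeric(p1), 1 / (1 + exp(-u1[2:4, 1])))
  expect_equal(p1[1, 1], 0.5)  # sigmoid at u = 0

  # outputs stay inside the saturation range for wild weights
  m$IW[] <- 10; m$OW[] <- 10; m$b2 <- 5
  p_wild <- forward_open_loop(m, u, y)
  expect_true(all(p_wild >= 0 & p_wild <= 1))
})

test_that("closed loop equals open loop when the model generated the data", {
  cfg <- narx_config(3, 2, n_n = 6, n_u = 2, n_y = 3)
  m <- init_model(cfg, 42)
  m$IW <- m$IW * 4; m$b2 <- c(0.4, 0.6)
  set.seed(10)
  u <- matrix(rnorm(60 * 3), 60, 3)
  w <- max(cfg$n_u - 1, cfg$n_y)
  cl <- forward_closed_loop(m, u)
  y_full <- rbind(matrix(0, w, 2), cl)
  ol <- forward_open_loop(m, u, y_full)
  expect_equal(ol, cl, tolerance = 1e-12)
})

test_that("closed loop with zero weights is constant and always bounded", {
  cfg <- narx_config(2, 1, n_n = 3, n_u = 2, n_y = 2)
  m <- init_model(cfg, 3)
  m$IW[] <- 0; m$OW[] <- 0; m$b2[] <- 0
  u <- matrix(rnorm(30 * 2), 30, 2)
  p <- forward_closed_loop(m, u)
  expect_true(all(p == 0))
  m2 <- init_model(cfg, 3)
  m2$IW <- m2$IW * 50; m2$OW <- m2$OW * 50
  p2 <- forward_closed_loop(m2, u * 100)
  expect_true(all(is.finite(p2)) && all(p2 >= 0 & p2 <= 1))
})

test_that("trial boundaries reset the delay windows", {
  cfg <- narx_config(2, 1, n_n = 4, n_u = 2, n_y = 2)
  m <- init_model(cfg, 5)
  set.seed(6)
  t1 <- list(inputs = matrix(rnorm(40), 20, 2),
             targets = matrix(runif(20), 20, 1))
  t2 <- list(inputs = matrix(rnorm(30), 15, 2),
             targets = matrix(runif(15), 15, 1))
  ns <- asNamespace("imnet")
  cw <- ns$collect_windows(cfg, list(t1, t2))
  sep <- rbind(ns$collect_windows(cfg, list(t1))$X,
               ns$collect_windows(cfg, list(t2))$X)
  expect_identical(cw$X, sep)
  p_joint <- ns$narx_mlp_forward(m, cw$X)
  p_sep <- rbind(forward_open_loop(m, t1$inputs, t1$targets),
                 forward_open_loop(m, t2$inputs, t2$targets))
  expect_equal(p_joint, p_sep)
})

test_that("model archives round-trip bit-exactly", {
  cfg <- narx_config(4, 3, n_l = 2, n_n = 5, n_u = 3, n_y = 2)
  m <- init_model(cfg, 99)
  m$in_center <- rnorm(asNamespace("imnet")$narx_input_dim(cfg))
  m$in_scale <- abs(rnorm(length(m$in_center))) + 0.5
  path <- withr::local_tempfile(fileext = ".json")
  save_narx(m, path)
  back <- load_narx(path)
  expect_identical(back$IW, m$IW)
  expect_identical(back$LW[[1]]$W, m$LW[[1]]$W)
  expect_identical(back$OW, m$OW)
  expect_identical(back$in_center, m$in_center)
  expect_equal(back$config, m$config)
  # predictions identical through the round trip
  X <- matrix(rnorm(10 * asNamespace("imnet")$narx_input_dim(cfg)), 10)
  expect_identical(asNamespace("imnet")$narx_mlp_forward(m, X),
                   asNamespace("imnet")$narx_mlp_forward(back, X))
})
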