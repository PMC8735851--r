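test_that("error metrics behave as defined", {
  y <- matrix(runif(40), 20, 2)
  expect_equal(mse(y, y), 0)
  expect_equal(mse(matrix(0, 5, 2), matrix(1, 5, 2)), 1)
  p <- y + 0.1
  expect_equal(mse(y, y + 0.3), 9 * mse(y, p))
  expect_error(mse(y, y[1:10, ]), class = "imnet_shape_error")

  expect_equal(regression_R(y, y), 100)
  yc <- y - mean(y)
  expect_equal(regression_R(yc, -yc), -100)
  expect_error(regression_R(matrix(1, 5, 1), matrix(runif(5))),
               class = "imnet_metric_error")
})

test_that("regression R of independent noise is near zero", {
  set.seed(14)
  a <- matrix(rnorm(1e4), ncol = 1)
  b <- matrix(rnorm(1e4), ncol = 1)
  expect_lt(abs(regression_R(a, b)), 5)
})

test_that("analytic Jacobian matches central differences", {
  ns <- asNamespace("imnet")
  cfg <- narx_config(2, 2, n_l = 2, n_n = 3, n_u = 2, n_y = 2)
  m <- init_model(cfg, 7)
  m$b1 <- runif(3, -0.1, 0.1); m$b2 <- c(0.4, 0.5)
  m$in_center <- rnorm(ns$narx_input_dim(cfg), 0, 0.1)
  m$in_scale <- runif(ns$narx_input_dim(cfg), 0.8, 1.2)
  set.seed(3)
  X <- matrix(rnorm(30 * ns$narx_input_dim(cfg)), 30)
  J <- ns$narx_jacobian(m, X)$J
  w0 <- ns$flatten_params(m)
  h <- 1e-6
  Jn <- vapply(seq_along(w0), function(i) {
    wp <- w0; wp[i] <- wp[i] + h
    wm <- w0; wm[i] <- wm[i] - h
    as.numeric(ns$narx_mlp_forward(ns$unflatten_params(m, wp), X) -
                 ns$narx_mlp_forward(ns$unflatten_params(m, wm), X)) / (2 * h)
  }, numeric(nrow(J)))
  expect_lt(max(abs(J - Jn)) / max(abs(Jn)), 1e-5)
})

test_that("LM training recovers the closed-form least-squares fit", {
  # identity activations, no feedback, unbounded output: the network is an
  # overparameterized affine map; at the optimum its composite coefficients
  # equal the ordinary least-squares solution
  cfg <- narx_config(3, 1, n_l = 1, n_n = 4, n_u = 1, n_y = 0,
                     hidden_activation = "identity",
                     output_range = c(-Inf, Inf))
  set.seed(19)
  U <- matrix(rnorm(300 * 3), 300, 3)
  beta <- c(1.5, -2, 0.7); alpha <- 0.3
  Y <- matrix(U %*% beta + alpha + 0.05 * rnorm(300), ncol = 1)
  st <- train_settings(max_epochs = 60, patience_epochs = 60,
                       standardize_inputs = FALSE)
  fit <- lm_train(init_model(cfg, 2), list(list(inputs = U, targets = Y)),
                  list(list(inputs = U, targets = Y)), settings = st)
  A <- as.numeric(fit$model$OW %*% fit$model$IW)
  c0 <- as.numeric(fit$model$OW %*% fit$model$b1 + fit$model$b2)
  ols <- stats::coef(stats::lm(Y ~ U))
  expect_equal(A, as.numeric(ols[-1]), tolerance = 1e-6)
  expect_equal(c0, as.numeric(ols[1]), tolerance = 1e-6)
})

test_that("accepted LM epochs never increase the training MSE", {
  cfg <- narx_config(2, 1, n_n = 5, n_u = 2, n_y = 2)
  set.seed(23)
  U <- matrix(rnorm(200 * 2), 200, 2)
  Y <- matrix(runif(200), ncol = 1)
  st <- train_settings(max_epochs = 15, patience_epochs = 15)
  fit <- lm_train(init_model(cfg, 4), list(list(inputs = U, targets = Y)),
                  list(list(inputs = U, targets = Y)), settings = st)
  expect_true(all(diff(fit$history$train_mse) <= 1e-14))
  expect_equal(fit$best_epoch, which.min(fit$history$val_mse))
  # returned model's validation MSE is the recorded minimum
  ns <- asNamespace("imnet")
  vw <- ns$collect_windows(cfg, list(list(inputs = U, targets = Y)))
  expect_equal(mse(vw$Y, ns$narx_mlp_forward(fit$model, vw$X)),
               min(fit$history$val_mse), tolerance = 1e-12)
})

test_that("LM in the heavy-damping limit steps along the gradient", {
  ns <- asNamespace("imnet")
  cfg <- narx_config(2, 1, n_n = 4, n_u = 1, n_y = 1)
  m <- init_model(cfg, 8)
  set.seed(31)
  X <- matrix(rnorm(50 * ns$narx_input_dim(cfg)), 50)
  Y <- matrix(runif(50), ncol = 1)
  jb <- ns$narx_jacobian(m, X)
  r <- as.numeric(jb$pred - Y)
  g <- as.numeric(crossprod(jb$J, r))
  mu <- 1e8
  step <- -solve(crossprod(jb$J) + diag(mu, length(g)), g)
  cosang <- sum(step * (-g)) / sqrt(sum(step^2) * sum(g^2))
  expect_gt(cosang, cos(1 * pi / 180))
})

test_that("validation patience stops training at best epoch + patience", {
  # replay: monotone improvement to epoch 34, flat afterwards
  trace <- c(seq(1, 0.1, length.out = 34), rep(0.1, 300))
  res <- replay_early_stopping(trace, patience_epochs = 100,
                               max_epochs = 200)
  expect_equal(res$best_epoch, 34)
  expect_equal(res$stop_epoch, 134)
  expect_equal(res$stop_reason, "patience")

  # end-to-end: plateaued training triggers patience in lm_train itself
  cfg <- narx_config(1, 1, n_n = 2, n_u = 1, n_y = 1)
  set.seed(12)
  U <- matrix(rnorm(80), 80, 1)
  Y <- matrix(runif(80), ncol = 1)
  st <- train_settings(max_epochs = 100, patience_epochs = 4)
  fit <- lm_train(init_model(cfg, 6), list(list(inputs = U, targets = Y)),
                  list(list(inputs = U, targets = Y * 0 + 0.5)),
                  settings = st)
  if (fit$stop_reason == "patience")
    expect_equal(nrow(fit$history), fit$best_epoch + 4)
  expect_true(fit$stop_reason %in% c("patience", "mu_max", "max_epochs"))
})

test_that("subject split is disjoint, covering, and seed-deterministic", {
  cohort <- lapply(1:17, function(i) list(id = i, trials = list()))
  s1 <- subject_split(cohort, 14, 2, 1, seed = 5)
  s2 <- subject_split(cohort, 14, 2, 1, seed = 5)
  s3 <- subject_split(cohort, 14, 2, 1, seed = 6)
  all_idx <- c(s1$indices$train, s1$indices$val, s1$indices$test)
  expect_equal(sort(all_idx), 1:17)
  expect_identical(s1$indices, s2$indices)
  expect_false(identical(s1$indices, s3$indices))
  expect_error(subject_split(cohort[1:10], 14, 2, 1),
               class = "imnet_data_error")
})
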