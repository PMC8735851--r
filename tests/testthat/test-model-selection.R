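test_that("grid enumeration is the flat Cartesian product", {
  full <- grid_spec()
  expect_length(enumerate_grid(full), 10 * 10 * 3 * 9)
  single <- grid_spec(n_u = 3, n_y = 5, n_l = 1, n_n = 20)
  cfgs <- enumerate_grid(single)
  expect_length(cfgs, 1)
  expect_s3_class(cfgs[[1]], "narx_config")
  small <- enumerate_grid(grid_spec(n_u = 1:2, n_y = 1:2, n_l = 1, n_n = 10))
  expect_true(all(vapply(small, function(c) c$n_n == 10, logical(1))))
})

test_that("grid search ranks deterministically with parameter-count tiebreak", {
  co <- tiny_teacher_cohort(n_subjects = 4, duration_s = 4, seed = 3)
  spec <- grid_spec(n_u = c(1, 3), n_y = c(1, 5), n_l = 1, n_n = 6)
  st <- train_settings(max_epochs = 4, patience_epochs = 4)
  r1 <- grid_search(spec, co$subjects, st, budget_epochs = 4,
                    split_sizes = c(2, 1, 1), seed = 2)
  r2 <- grid_search(spec, co$subjects, st, budget_epochs = 4,
                    split_sizes = c(2, 1, 1), seed = 2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 4)
  # ranking is by all-data R descending
  expect_true(all(diff(r1$all_R) <= 0))
  # recorded parameter counts delegate to the counting formula
  for (i in seq_len(nrow(r1)))
    expect_identical(r1$parameter_count[i],
                     count_parameters(narx_config(5, 6, r1$n_l[i], r1$n_n[i],
                                                  r1$n_u[i], r1$n_y[i])))
})

test_that("subject-wise k-fold CV partitions subjects and averages folds", {
  co <- tiny_teacher_cohort(n_subjects = 3, duration_s = 4, seed = 5)
  cfg <- narx_config(5, 6, n_n = 5, n_u = 2, n_y = 2)
  st <- train_settings(max_epochs = 3, patience_epochs = 3)
  cv <- kfold_cv(co$subjects, cfg, k = 3, settings = st, seed = 4)
  expect_length(cv$fold_R, 3)
  expect_equal(sort(unname(unlist(cv$folds))), 1:3)
  expect_identical(cv$average, mean(cv$fold_R))
  expect_true(cv$average >= cv$min && cv$average <= cv$max)
  expect_error(kfold_cv(co$subjects, cfg, k = 5, settings = st),
               class = "imnet_data_error")
})

test_that("per-channel ranking puts a clean mapping above pure noise", {
  set.seed(77)
  n <- 400
  subjects <- lapply(1:2, function(s) {
    U <- vapply(1:5, function(j) smooth_signal(n, seed = 50 * s + j),
                numeric(n))
    colnames(U) <- paste0("in", 1:5)
    clean <- 1 / (1 + exp(-3 * scale(U[, 1] + U[, 2])))
    noise <- runif(n)
    targets <- cbind(CLEAN = as.numeric(clean), NOISE = noise)
    list(id = s, trials = list(list(inputs = U, targets = targets)))
  })
  cfg <- narx_config(5, 2, n_n = 6, n_u = 2, n_y = 2)
  st <- train_settings(max_epochs = 8, patience_epochs = 8)
  rank <- per_channel_evaluation(subjects, cfg, st, top_m = 1, seed = 3)
  expect_equal(nrow(rank), 2)
  expect_equal(rank$channel[1], "CLEAN")
  expect_gt(rank$R[1], rank$R[2])
  expect_identical(attr(rank, "selected"), "CLEAN")
})

test_that("backward selection visits nested subsets and one drop per phase", {
  cohort <- planted_cohort(n_subjects = 1, n = 300, active = c(1, 2),
                           seed = 2)
  cfg <- narx_config(5, 1, n_n = 5, n_u = 2, n_y = 2)
  st <- train_settings(max_epochs = 5, patience_epochs = 5)
  rep <- backward_selection(cohort, cfg, use_recurrent = FALSE,
                            settings = st, seed = 1)
  ph <- rep$phases
  # phase 1 is the full-set baseline; phases 2..5 evaluate leave-one-out
  expect_equal(max(ph$phase), 5)
  expect_equal(sum(ph$phase == 1), 1)
  for (k in 2:5) expect_equal(sum(ph$phase == k), 5 - (k - 2) - 1 + 1)
  # dominance is a permutation of the input names
  expect_setequal(rep$dominance, paste0("in", 1:5))
  expect_length(rep$elimination_order, 4)
  # subsets shrink by exactly one input per phase and are nested
  active_sets <- lapply(2:5, function(k)
    strsplit(ph$active[ph$phase == k][1], "\\+")[[1]])
  sizes <- vapply(active_sets, length, integer(1))
  expect_equal(sizes, c(4, 3, 2, 1))
})

test_that("ANN mode uses direct taps and RNN mode keeps the delays", {
  cohort <- planted_cohort(n_subjects = 1, n = 200, seed = 3)
  cfg <- narx_config(5, 1, n_n = 4, n_u = 3, n_y = 4)
  st <- train_settings(max_epochs = 3, patience_epochs = 3)
  rep_ann <- backward_selection(cohort, cfg, use_recurrent = FALSE,
                                settings = st, seed = 2)
  rep_rnn <- backward_selection(cohort, cfg, use_recurrent = TRUE,
                                settings = st, seed = 2)
  expect_equal(rep_ann$mode, "ANN")
  expect_equal(rep_rnn$mode, "RNN")
  expect_setequal(rep_rnn$dominance, paste0("in", 1:5))
})
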