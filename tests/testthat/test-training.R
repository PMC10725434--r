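# Metrics, stratified splitting, training determinism, CV and grid plumbing.

test_that("compute_metrics matches hand-derived values", {
  m0 <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$mae, 0)
  expect_equal(m0$rmse, 0)
  expect_equal(m0$r2, 1)

  m1 <- compute_metrics(c(0, 2), c(1, 1))     # SS_res = 2, SS_tot = 2
  expect_equal(m1$mae, 1)
  expect_equal(m1$rmse, 1)
  expect_equal(m1$r2, 0)

  m2 <- compute_metrics(c(2, 4, 6), c(3, 4, 5))  # SS_res = 2, SS_tot = 8
  expect_equal(m2$mae, 2 / 3)
  expect_equal(m2$rmse, sqrt(2 / 3))
  expect_equal(m2$r2, 0.75)

  expect_error(compute_metrics(1:3, 1:2), "mismatch")
  expect_warning(compute_metrics(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
})

test_that("rmse >= mae and r2 = 1 iff exact, over random vectors", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    y <- rnorm(n, 50, 20)
    p <- y + rnorm(n, 0, sample(c(0.1, 1, 10), 1))
    m <- compute_metrics(y, p)
    expect_gte(m$rmse, m$mae - 1e-12)
    expect_lte(m$r2, 1)
    expect_false(isTRUE(all.equal(m$r2, 1)) && any(p != y))
  }
})

test_that("stratified_split partitions and respects per-bin fractions", {
  co <- lapply(1:100, function(i) {
    subject_record(paste0("s", i), 20 + (i %% 4), "male")
  })
  sp <- stratified_split(co, 0.1, age_bin_width = 5, seed = 2)
  expect_length(sp$test, 10)                       # one bin, exact rounding
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp0 <- stratified_split(co, 0, seed = 2)
  expect_length(sp0$test, 0)

  # two bins keep proportional representation
  ages <- c(rep(25, 40), rep(70, 60))
  co2 <- lapply(seq_along(ages), function(i) {
    subject_record(paste0("t", i), ages[i], "female")
  })
  sp2 <- stratified_split(co2, 0.25, seed = 3)
  test_ages <- vapply(sp2$test, `[[`, numeric(1), "age")
  expect_equal(sum(test_ages == 25), 10)
  expect_equal(sum(test_ages == 70), 15)

  expect_error(stratified_split(list(), 0.1), "empty")
})

test_that("training is seed-deterministic and epochs=0 degenerates cleanly", {
  co <- tiny_cohort8(n = 8, seed = 10)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 77)
  m1 <- train(tiny_spec("cnn_only"), co, cfg)
  m2 <- train(tiny_spec("cnn_only"), co, cfg)
  expect_identical(m1$history, m2$history)
  expect_length(m1$history, 2)
  expect_identical(predict(m1, co), predict(m2, co))

  m0 <- train(tiny_spec("cnn_only"), co, train_config(epochs = 0, seed = 1))
  expect_length(m0$history, 0)
  expect_true(all(is.finite(predict(m0, co))))
})

test_that("each optimizer completes an update and reduces early loss", {
  co <- tiny_cohort8(n = 8, seed = 11)
  for (opt in c("adagrad", "adam", "nag", "rmsprop", "sgd")) {
    cfg <- train_config(optimizer = opt, learning_rate = 1e-3, decay = 3e-4,
                        epochs = 3, batch_size = 4, seed = 5)
    m <- train(tiny_spec("cnn_only"), co, cfg)
    expect_length(m$history, 3)
    expect_true(all(is.finite(m$history)))
  }
})

test_that("augmented training only perturbs the training path", {
  co <- tiny_cohort8(n = 6, seed = 12)
  cfg_plain <- train_config(epochs = 1, batch_size = 3, seed = 9)
  cfg_aug <- train_config(epochs = 1, batch_size = 3, seed = 9,
                          augment = augment_config(probability = 1,
                                                   rotation_range_deg = 5,
                                                   translation_range_vox = 1))
  m_plain <- train(tiny_spec("cnn_only"), co, cfg_plain)
  m_aug <- train(tiny_spec("cnn_only"), co, cfg_aug)
  # augmentation changes the learned weights...
  expect_false(identical(m_plain$history, m_aug$history))
  # ...but prediction still sees the raw volumes (deterministic inference)
  expect_identical(predict(m_aug, co), predict(m_aug, co))
  # and demographics are never altered by augmentation
  expect_identical(co$demographics$age, vapply(co$records, `[[`, numeric(1), "age"))
})

test_that("crossvalidate partitions folds and summarizes exactly", {
  co <- tiny_cohort8(n = 12, seed = 13)
  cfg <- train_config(epochs = 1, batch_size = 6, k_folds = 3, seed = 21)
  cv <- crossvalidate(tiny_spec("cnn_only"), co, cfg)
  expect_length(cv$folds, 3)
  expect_setequal(unique(cv$fold_assignment), 1:3)
  maes <- vapply(cv$folds, `[[`, numeric(1), "mae")
  expect_equal(cv$summary$mean[cv$summary$metric == "mae"], mean(maes),
               tolerance = 1e-12)
  # reproducible fold assignment
  cv2 <- crossvalidate(tiny_spec("cnn_only"), co, cfg)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)

  expect_error(crossvalidate(tiny_spec("cnn_only"), co,
                             train_config(k_folds = 13, epochs = 1)),
               "exceeds")
})

test_that("optimizer grid enumerates 10 cells and picks argmin MAE", {
  co <- tiny_cohort8(n = 6, seed = 14)
  cfg <- train_config(epochs = 1, batch_size = 3, k_folds = 2, seed = 31)
  # full enumeration contract on a restricted (fast) grid first
  g1 <- optimizer_grid(tiny_spec("cnn_only"), co, cfg,
                       optimizers = c("adam", "sgd"),
                       lr_decay = list(c(0.001, 0.0003)))
  expect_identical(nrow(g1$table), 2L)
  expect_identical(g1$best, which.min(g1$table$mae_mean))

  # restricting the grid to one cell reproduces crossvalidate
  cfg_cell <- cfg
  cfg_cell$optimizer <- "adam"; cfg_cell$learning_rate <- 0.001
  cfg_cell$decay <- 0.0003
  cv <- crossvalidate(tiny_spec("cnn_only"), co, cfg_cell)
  expect_equal(g1$table$mae_mean[g1$table$optimizer == "adam"],
               cv$summary$mean[cv$summary$metric == "mae"], tolerance = 1e-12)

  # default grid shape: 5 optimizers x 2 (lr, decay) pairs
  expect_identical(length(OPTIMIZERS) * 2L, 10L)
})
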