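# Architecture construction, shape arithmetic, prediction contracts.

test_that("conv feature shapes follow repeated floor-halving", {
  s <- model_spec("cnn_mlp", input_shape = c(105, 127, 105), n_conv_blocks = 5)
  expect_identical(s$conv_shapes[[6]], c(3L, 3L, 3L))
  # intermediate chain for one axis: 127 -> 63 -> 31 -> 15 -> 7 -> 3
  expect_identical(vapply(s$conv_shapes, `[`, integer(1), 2),
                   c(127L, 63L, 31L, 15L, 7L, 3L))

  s8 <- model_spec("cnn_only", input_shape = c(8, 8, 8), n_conv_blocks = 3)
  expect_identical(s8$conv_shapes[[4]], c(1L, 1L, 1L))

  err <- tryCatch(model_spec("cnn_only", input_shape = c(8, 4, 8),
                             n_conv_blocks = 3),
                  error = function(e) conditionMessage(e))
  expect_match(err, "axis 2")
})

test_that("channel doubling and head width invariants hold", {
  s <- tiny_spec(blocks = 2)
  pred <- build_model(s, init_seed = 1)
  convs <- Filter(function(l) l$kind == "conv", pred$image_layers)
  expect_identical(vapply(convs, `[[`, integer(1), "c_out"), c(2L, 4L))
  last_dense <- pred$head_layers[[length(pred$head_layers)]]
  expect_identical(ncol(last_dense$W), 1L)
})

test_that("prediction is deterministic, ordered, and shape-checked", {
  co <- tiny_cohort8(n = 4, seed = 1)
  pred <- build_model(tiny_spec(), init_seed = 5)
  y1 <- predict(pred, co)
  y2 <- predict(pred, co)
  expect_identical(y1, y2)
  expect_length(y1, 4)
  expect_true(all(is.finite(y1)))

  # reproducible across fresh builds with the same init seed
  y3 <- predict(build_model(tiny_spec(), init_seed = 5), co)
  expect_identical(y1, y3)

  # batch order contract
  yrev <- predict(pred, rev(co$records))
  expect_equal(yrev, rev(y1), tolerance = 1e-12)

  # shape mismatch is named
  expect_error(predict(pred, tiny_cohort(n = 1)), "16x16x16|8x8x8")
})

test_that("cnn_only ignores sex; cnn_mlp and cnn_linear_sex respond to it", {
  co <- tiny_cohort8(n = 2, seed = 2)
  rec <- co$records[[1]]
  flip <- subject_record(rec$id, rec$age,
                         if (rec$sex == "male") "female" else "male",
                         rec$volume)
  for (variant in c("cnn_only", "cnn_mlp", "cnn_linear_sex")) {
    # an individual random init can have a dead sex branch, so probe several
    diffs <- vapply(1:5, function(s) {
      y <- predict(build_model(tiny_spec(variant), init_seed = s), list(rec, flip))
      abs(y[1] - y[2])
    }, numeric(1))
    if (variant == "cnn_only") {
      expect_true(all(diffs == 0))
    } else {
      expect_gt(max(diffs), 0)
    }
  }
})

test_that("cnn_mlp with a silenced sex branch reproduces cnn_only", {
  # equivalence oracle: zero the sex-derived rows of the fusion head and
  # copy the shared image-path + head weights into a cnn_only model
  co <- tiny_cohort8(n = 3, seed = 4)
  mlp <- build_model(tiny_spec("cnn_mlp"), init_seed = 11)
  only <- build_model(tiny_spec("cnn_only"), init_seed = 99)
  only$image_layers <- mlp$image_layers
  img_dim <- mlp$img_dim
  h1 <- mlp$head_layers[[1]]
  h1$W <- h1$W[seq_len(img_dim), , drop = FALSE]      # drop sex rows
  only$head_layers <- list(h1, mlp$head_layers[[2]], mlp$head_layers[[3]])
  # silence the sex branch inside the cnn_mlp
  nh <- nrow(mlp$head_layers[[1]]$W)
  mlp$head_layers[[1]]$W[(img_dim + 1):nh, ] <- 0
  expect_equal(predict(mlp, co), predict(only, co), tolerance = 1e-12)
})

test_that("untrained output is finite and unbounded-linear at the head", {
  pred <- build_model(tiny_spec("cnn_only"), init_seed = 8)
  co <- tiny_cohort8(n = 2, seed = 6)
  # scaling the final layer scales the output: no saturating activation
  y0 <- predict(pred, co)
  pred$head_layers[[3]]$W <- pred$head_layers[[3]]$W * 100
  pred$head_layers[[3]]$b <- pred$head_layers[[3]]$b * 100
  y1 <- predict(pred, co)
  expect_equal(y1, y0 * 100, tolerance = 1e-8)
})
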