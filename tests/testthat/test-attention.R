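# Grad-CAM for regression: closed-form oracle, normalization rules,
# averaging and sex-difference maps.

test_that("gradcam matches the closed-form linear toy oracle", {
  alpha <- c(0.7, -0.2)
  pred <- linear_toy_model(alpha = alpha)
  rec <- toy_record()
  x <- rec$volume$data

  # independent oracle computed directly from the formula above
  expected <- pmax((alpha[1] / 8) * x + (alpha[2] / 8) * (2 * x), 0)

  cam <- gradcam(pred, rec, layer = 1, normalize = "raw")
  expect_identical(dim(cam$data), dim(x))
  expect_lt(max(abs(cam$data - expected)), 1e-5)

  # and the model really is the linear functional it claims to be
  y <- predict(pred, list(rec))
  pool <- brainage3d:::make_pool_idx(c(4L, 4L, 4L))$idx
  pooled_max <- apply(matrix(x[pool], ncol = 8), 1, max)
  expect_equal(y, 100 + sum(alpha[1] * pooled_max) + sum(alpha[2] * 2 * pooled_max),
               tolerance = 1e-6)
})

test_that("normalization rules: minmax to [0,1], all-equal maps to zeros", {
  pred <- linear_toy_model(alpha = c(0.5, 0.1))
  rec <- toy_record(seed = 4)
  cam <- gradcam(pred, rec, layer = 1)
  expect_equal(min(cam$data), 0)
  expect_equal(max(cam$data), 1)

  # uniform positive input -> constant raw map -> all-zero normalized map
  flat <- subject_record("flat", 50, "male",
                         volume_image(array(1, dim = c(4, 4, 4))))
  cam_flat <- gradcam(pred, flat, layer = 1)
  expect_true(all(cam_flat$data == 0))

  expect_error(gradcam(pred, rec, layer = 5), "1\\.\\.1")
})

test_that("attention is invariant to inference batch composition", {
  co <- tiny_cohort8(n = 3, seed = 21)
  pred <- build_model(tiny_spec("cnn_only"), init_seed = 9)
  solo <- gradcam(pred, co$records[[1]])
  # predict on a batch first (warms nothing: BN uses running stats), then re-map
  invisible(predict(pred, co))
  again <- gradcam(pred, co$records[[1]])
  expect_identical(solo$data, again$data)
})

test_that("average and difference maps follow their arithmetic contracts", {
  d <- c(4L, 4L, 4L)
  m0 <- attention_map(array(0, dim = d))
  m1 <- attention_map(array(1, dim = d))
  avg <- average_attention(list(m0, m1))
  expect_true(all(avg$data == 0.5))
  expect_identical(average_attention(list(m1))$data, m1$data)

  set.seed(9)
  maps <- lapply(1:4, function(i) attention_map(array(runif(64), dim = d)))
  av <- average_attention(maps)$data
  lo <- pmin(maps[[1]]$data, maps[[2]]$data, maps[[3]]$data, maps[[4]]$data)
  hi <- pmax(maps[[1]]$data, maps[[2]]$data, maps[[3]]$data, maps[[4]]$data)
  expect_true(all(av >= lo - 1e-12 & av <= hi + 1e-12))

  # identical group means -> constant difference -> zeros
  dm <- difference_attention(list(m1), list(m1))
  expect_true(all(dm$data == 0))

  # antisymmetry of the raw (pre-normalization) difference
  a <- list(attention_map(array(runif(64), dim = d)))
  b <- list(attention_map(array(runif(64), dim = d)))
  fwd <- difference_attention(a, b, normalize = "raw")$data
  rev_ <- difference_attention(b, a, normalize = "raw")$data
  expect_equal(fwd, -rev_, tolerance = 1e-12)

  # a single contrived hot voxel is the unique 1.0 after normalization
  hot <- array(0, dim = d); hot[2, 3, 1] <- 0.9
  dn <- difference_attention(list(attention_map(hot)), list(m0))$data
  expect_equal(dn[2, 3, 1], 1)
  expect_equal(sum(dn == 1), 1)
  expect_equal(sum(dn != 0), 1)

  expect_error(average_attention(list()), "empty")
  expect_error(difference_attention(list(), list(m0)), "nonempty")
})

test_that("attention maps write as NIfTI on the input grid", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  m <- attention_map(array(runif(64), dim = c(4, 4, 4)))
  m$data <- brainage3d:::minmax_norm(m$data)
  write_attention(m, path, spacing = c(10, 10, 10))
  back <- read_volume(path)
  expect_equal(back$data, m$data, tolerance = 1e-6)
  expect_identical(back$spacing, c(10, 10, 10))
})
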