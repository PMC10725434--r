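# Phantom generator: determinism, age/sex morphology, cohorts, augmentation.

test_that("phantom generation is deterministic and age-monotone", {
  p <- quiet_params()
  a <- generate_phantom(50, "male", p, subject_seed = 7)
  b <- generate_phantom(50, "male", p, subject_seed = 7)
  expect_identical(a$data, b$data)

  # noisy path is deterministic too, and seed-sensitive
  pn <- phantom_params(noise_sd = 0.05)
  n1 <- generate_phantom(50, "male", pn, subject_seed = 7)
  n2 <- generate_phantom(50, "male", pn, subject_seed = 7)
  n3 <- generate_phantom(50, "male", pn, subject_seed = 8)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))

  # ventricle (dark center) grows with age
  v20 <- generate_phantom(20, "female", p, 1)
  v80 <- generate_phantom(80, "female", p, 1)
  expect_gt(sum(v80$data < 0.15), sum(v20$data < 0.15))

  # monotone over a grid of ages
  counts <- vapply(seq(20, 90, by = 10), function(age) {
    sum(generate_phantom(age, "female", p, 1)$data < 0.15)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("measured shell thickness tracks the analytic formula", {
  p <- quiet_params(grid_shape = c(32L, 32L, 32L))
  measure <- function(age) {
    vol <- generate_phantom(age, "female", p, 1)
    d <- dim(vol$data)
    ctr <- floor((d + 1) / 2)
    ray <- vol$data[ctr[1]:d[1], ctr[2], ctr[3]]       # +x ray through center
    sum(ray > 0.75) * vol$spacing[1]
  }
  for (age in c(20, 80)) {
    expected <- p$shell_base_thickness + p$shell_age_slope * age
    expect_lt(abs(measure(age) - expected), 1.5 * p$spacing_mm)
  }
  expect_gt(measure(20), measure(80))
})

test_that("sexes differ only inside the designated frontal subregion", {
  p <- quiet_params()
  m <- generate_phantom(40, "male", p, 1)
  f <- generate_phantom(40, "female", p, 1)
  region <- brainage3d:::phantom_sex_region(p)
  expect_true(all(m$data[!region] == f$data[!region]))
  expect_gt(sum(m$data[region] != f$data[region]), 0)
})

test_that("age bounds and degenerate geometry are rejected", {
  p <- quiet_params()
  expect_error(generate_phantom(17, "male", p, 1), "\\[18, 90\\]")
  expect_error(generate_phantom(95, "male", p, 1), "\\[18, 90\\]")
  expect_error(phantom_params(shell_base_thickness = 5, shell_age_slope = -0.15),
               "thickness")
  expect_error(phantom_params(ventricle_age_slope = 0.8), "shell|ventricle")
  expect_error(phantom_params(grid_shape = c(8, 8, 8)), ">= 16")
})

test_that("cohorts are reproducible with sane demographics", {
  p <- quiet_params()
  c1 <- generate_cohort(10, 20, 80, 0.5, p, seed = 9)
  c2 <- generate_cohort(10, 20, 80, 0.5, p, seed = 9)
  expect_identical(c1$demographics, c2$demographics)
  expect_identical(c1$records[[3]]$volume$data, c2$records[[3]]$volume$data)

  # degenerate age interval
  c3 <- generate_cohort(3, 40, 40, 0.5, p, seed = 1)
  expect_equal(c3$demographics$age, rep(40, 3))

  # sex draw within binomial 99% interval (n = 1000 demographics only:
  # reuse the draw logic without building volumes)
  draws <- brainage3d:::with_seed_(123, stats::runif(1000) < 0.5)
  lim <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(sum(draws), lim[1])
  expect_lte(sum(draws), lim[2])

  expect_error(generate_cohort(0, 20, 80, 0.5, p, 1), "positive")
})

test_that("cohort male counts follow the requested fraction", {
  p <- quiet_params()
  co <- generate_cohort(40, 20, 80, 0.7, p, seed = 3)
  males <- sum(co$demographics$sex == "male")
  lim <- qbinom(c(0.005, 0.995), 40, 0.7)
  expect_gte(males, lim[1])
  expect_lte(males, lim[2])
})

test_that("augment honors probability, bounds, and the shift convention", {
  vol <- rand_volume(c(16, 16, 16))
  # probability 0: untouched
  cfg0 <- augment_config(probability = 0)
  expect_identical(augment(vol, cfg0, 1)$data, vol$data)

  # forced translation +1 along axis 1 == direct array shift
  shifted <- apply_rigid(vol, c(0, 0, 0), c(1, 0, 0))
  manual <- array(0, dim = dim(vol$data))
  manual[1:15, , ] <- vol$data[2:16, , ]
  expect_equal(shifted$data, manual, tolerance = 1e-12)

  # shape contract + determinism over many draws
  cfg <- augment_config(probability = 1, rotation_range_deg = 10,
                        translation_range_vox = 3)
  for (s in 1:5) {
    a1 <- augment(vol, cfg, s)
    a2 <- augment(vol, cfg, s)
    expect_identical(dim(a1$data), dim(vol$data))
    expect_identical(a1$data, a2$data)
  }

  # probability is honored on average (seeded draws, fixed expectation)
  hits <- vapply(1:200, function(s) {
    !identical(augment(vol, augment_config(probability = 0.3), s)$data, vol$data)
  }, logical(1))
  lim <- qbinom(c(0.005, 0.995), 200, 0.3)
  expect_gte(sum(hits), lim[1])
  expect_lte(sum(hits), lim[2])
})

test_that("pure rotation preserves content mass approximately", {
  p <- quiet_params()
  vol <- generate_phantom(50, "female", p, 1)
  rot <- apply_rigid(vol, c(5, -7, 3), c(0, 0, 0))
  expect_identical(dim(rot$data), dim(vol$data))
  expect_lt(abs(sum(rot$data) - sum(vol$data)) / sum(vol$data), 0.05)
})

test_that("cohort write/read round-trips volumes and demographics", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(n = 3, seed = 5)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "demographics.tsv")))
  back <- read_cohort(dir)
  expect_equal(back$demographics$age, co$demographics$age, tolerance = 1e-6)
  expect_equal(back$records[[2]]$volume$data, co$records[[2]]$volume$data,
               tolerance = 1e-5)
})
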