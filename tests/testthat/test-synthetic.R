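test_that("the generated label is built as specified", {
  ds <- small_linear_dataset(n = 800, d = 40, k = 8, noise_sd = 0.5, seed = 1)
  expect_equal(sd(ds$scores$score), 1, tolerance = 1e-6) # explicit rescale
  expect_equal(nrow(ds$truth$informative), 8)
  expect_equal(ds$truth$r_max, 1 / sqrt(1 + 0.25), tolerance = 1e-12)
})

test_that("noise-free data lets an oracle linear predictor reach r ~ 1", {
  ds <- small_linear_dataset(n = 500, d = 30, k = 6, noise_sd = 0, seed = 2)
  expect_equal(ds$truth$r_max, 1)
  expect_gte(pearson_r(ds$scores$score, ds$truth$signal), 0.999)
})

test_that("the closed-form ceiling matches the sample correlation at large n", {
  # signal variance 1, noise variance 1 -> r_max = 1/sqrt(2)
  spec <- synthetic_spec(4000, n_features = 100, n_informative = 10,
                         n_measures = 1, noise_sd = 1, zero_inflation = 0,
                         seed = 4)
  ds <- generate_dataset(spec)
  expect_equal(ds$truth$r_max, 1 / sqrt(2), tolerance = 1e-12)
  r_sample <- pearson_r(ds$scores$score, ds$truth$signal)
  expect_lt(abs(r_sample - 1 / sqrt(2)), 0.03)
})

test_that("noise_sd_for_ceiling inverts the ceiling formula", {
  for (r in c(0.3, 0.6, 0.9, 1)) {
    expect_equal(1 / sqrt(1 + noise_sd_for_ceiling(r)^2), r, tolerance = 1e-12)
  }
  expect_error(noise_sd_for_ceiling(0), "in \\(0, 1\\]")
})

test_that("zero-inflation hits the requested entry fraction", {
  spec <- synthetic_spec(1000, n_features = 100, n_informative = 10,
                         n_measures = 1, zero_inflation = 0.1, seed = 5)
  ds <- generate_dataset(spec)
  zero_frac <- mean(as.matrix(ds$tables[[1]][-1]) == 0)
  expect_lt(abs(zero_frac - 0.1), 0.01) # binomial tolerance at n*d = 1e5
})

test_that("measures sit on their characteristic scales", {
  ds <- generate_dataset(synthetic_spec(300, n_features = 50, n_informative = 5,
                                        zero_inflation = 0, seed = 6))
  expect_equal(names(ds$tables), c("FA", "MD", "NoS"))
  fa <- as.matrix(ds$tables$FA[-1])
  md <- as.matrix(ds$tables$MD[-1])
  expect_true(mean(fa) > 0.4 && mean(fa) < 0.6)
  expect_true(mean(md) > 5e-4 && mean(md) < 1.2e-3)
  # informative features split across the three measures
  expect_equal(sort(unique(ds$truth$informative$measure)), sort(names(ds$tables)))
})

test_that("generation is deterministic and fixtures round-trip exactly", {
  spec <- synthetic_spec(40, n_features = 12, n_informative = 3,
                         zero_inflation = 0.05, seed = 9)
  ds1 <- generate_dataset(spec)
  ds2 <- generate_dataset(spec)
  expect_identical(ds1$scores, ds2$scores)
  expect_identical(ds1$tables, ds2$tables)

  dir <- withr::local_tempdir()
  write_dataset(ds1, dir)
  # byte-identical files under a fixed seed
  dir2 <- withr::local_tempdir()
  write_dataset(generate_dataset(spec), dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
  back <- read_dataset(dir)
  for (m in names(ds1$tables)) {
    expect_equal(as.matrix(back$tables[[m]][-1]), as.matrix(ds1$tables[[m]][-1]))
  }
  expect_equal(back$scores$score, ds1$scores$score)
  expect_equal(back$truth$r_max, ds1$truth$r_max)
  expect_equal(back$category_map, ds1$category_map)
})

test_that("the category map covers every feature with the five categories", {
  ds <- generate_dataset(synthetic_spec(20, n_features = 953, n_informative = 10,
                                        n_measures = 1, seed = 3))
  expect_equal(nrow(ds$category_map), 953)
  expect_setequal(unique(ds$category_map$category),
                  c("association", "projection", "commissural",
                    "cerebellar", "superficial"))
  expect_setequal(ds$category_map$feature_id, names(ds$tables[[1]])[-1])
})

test_that("the nonlinear variant still has unit-sd labels and valid truth", {
  spec <- synthetic_spec(600, n_features = 30, n_informative = 6,
                         n_measures = 1, nonlinear = TRUE, zero_inflation = 0,
                         seed = 8)
  ds <- generate_dataset(spec)
  expect_equal(sd(ds$scores$score), 1, tolerance = 1e-6)
  expect_gt(pearson_r(ds$scores$score, ds$truth$signal), 0.5)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(10, n_features = 5, n_informative = 6), "exceed")
  expect_error(synthetic_spec(10, zero_inflation = 1), "zero_inflation")
  expect_error(synthetic_spec(10, noise_sd = -1), "noise_sd")
})
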