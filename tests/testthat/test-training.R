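test_that("training is deterministic under a fixed seed", {
  ds <- small_linear_dataset(n = 120, d = 10, k = 3, seed = 2)
  sp <- make_split(120, seed = 1)
  fit1 <- scr_fit(ds$tables[[1]], ds$scores, sp,
                  pretrain_batch = 64, hidden_dim = 16, max_epochs = 8, seed = 5)
  fit2 <- scr_fit(ds$tables[[1]], ds$scores, sp,
                  pretrain_batch = 64, hidden_dim = 16, max_epochs = 8, seed = 5)
  expect_identical(fit1$encoder, fit2$encoder)
  expect_identical(fit1$regressor, fit2$regressor)
  expect_identical(fit1$history, fit2$history)
  p <- predict(fit1, ds$tables[[1]])
  expect_identical(p, predict(fit1, ds$tables[[1]])) # prediction is pure
  expect_identical(p, predict(fit2, ds$tables[[1]]))
})

test_that("fine-tuning leaves the encoder parameters bit-identical", {
  ds <- small_linear_dataset(n = 150, d = 12, k = 3, seed = 4)
  sp <- make_split(150, seed = 2)
  pre <- scr_pretrain_encoder(ds$tables[[1]], ds$scores, sp,
                              pretrain_batch = 64, hidden_dim = 16,
                              max_epochs = 6, seed = 3)
  checksum_before <- serialize(pre$encoder, NULL)
  model <- scr_finetune(pre, ds$tables[[1]], ds$scores)
  expect_identical(serialize(pre$encoder, NULL), checksum_before)
  expect_identical(model$encoder, pre$encoder) # carried over untouched
})

test_that("contrastive training reduces the training loss on a linear task", {
  improved <- vapply(1:3, function(s) {
    ds <- small_linear_dataset(n = 560, d = 20, k = 5, seed = 30 + s)
    sp <- make_split(560, seed = s)
    pre <- scr_pretrain_encoder(ds$tables[[1]], ds$scores, sp,
                                pretrain_batch = 128, patience = 5,
                                max_epochs = 25, seed = s)
    h <- pre$history
    h$train_loss[nrow(h)] < h$train_loss[1]
  }, logical(1))
  expect_true(all(improved))
})

test_that("the pipeline recovers a noise-free linear signal", {
  ds <- small_linear_dataset(n = 2000, d = 50, k = 10, noise_sd = 0, seed = 3)
  sp <- make_split(2000, seed = 5)
  fit <- scr_fit(ds$tables[[1]], ds$scores, sp, seed = 7)
  r_test <- pearson_r(ds$scores$score[sp$test],
                      predict(fit, ds$tables[[1]][sp$test, ]))
  expect_gte(r_test, 0.95)
  r_train <- pearson_r(ds$scores$score[sp$train],
                       predict(fit, ds$tables[[1]][sp$train, ]))
  expect_gte(r_train, 0.95)
})

test_that("constant labels produce near-constant predictions", {
  tbl <- tiny_feature_table(120, 8, seed = 6)
  scores <- tibble::tibble(subject_id = tbl$subject_id, score = rep(1.5, 120))
  sp <- make_split(120, seed = 1)
  fit <- scr_fit(tbl, scores, sp, pretrain_batch = 32, hidden_dim = 16,
                 finetune_batch = 16, learning_rate = 0.01,
                 max_epochs = 80, seed = 2)
  pred <- predict(fit, tbl)
  expect_lt(sd(pred), 0.05)
  expect_lt(mean((pred - 1.5)^2), 0.05) # fitted MSE ~ label variance = 0
})

test_that("prediction is row-wise: permuting rows permutes the output", {
  ds <- small_linear_dataset(n = 100, d = 8, k = 2, seed = 8)
  sp <- make_split(100, seed = 3)
  fit <- scr_fit(ds$tables[[1]], ds$scores, sp, pretrain_batch = 64,
                 hidden_dim = 16, max_epochs = 5, seed = 4)
  tbl <- ds$tables[[1]]
  perm <- withr::with_seed(9, sample(nrow(tbl)))
  expect_equal(predict(fit, tbl[perm, ]), predict(fit, tbl)[perm])
})

test_that("prediction rejects mismatched feature ids", {
  ds <- small_linear_dataset(n = 80, d = 6, k = 2, seed = 10)
  sp <- make_split(80, seed = 1)
  fit <- scr_fit(ds$tables[[1]], ds$scores, sp, pretrain_batch = 32,
                 hidden_dim = 8, max_epochs = 3, seed = 1)
  bad <- ds$tables[[1]]
  names(bad)[2] <- "not_a_cluster"
  expect_error(predict(fit, bad), "feature ids")
})

test_that("the reference MLP learns a small noise-free task", {
  ds <- small_linear_dataset(n = 800, d = 20, k = 5, noise_sd = 0, seed = 12)
  sp <- make_split(800, seed = 2)
  fit <- mlp_fit(ds$tables[[1]], ds$scores, sp, seed = 3)
  r <- pearson_r(ds$scores$score[sp$test], predict(fit, ds$tables[[1]][sp$test, ]))
  expect_gte(r, 0.9)
  # determinism for the baseline too
  fit2 <- mlp_fit(ds$tables[[1]], ds$scores, sp, seed = 3)
  expect_identical(fit$net, fit2$net)
})
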