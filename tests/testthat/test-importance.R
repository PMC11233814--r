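# Most importance tests run against a transparent linear model so that the
# permutation bookkeeping is exercised without network-training time.
make_linear_setup <- function(n = 300, d = 30, k = 5, seed = 1) {
  ds <- small_linear_dataset(n = n, d = d, k = k, noise_sd = 0.3, seed = seed)
  tbl <- ds$tables[[1]]
  x <- as.matrix(tbl[-1])
  coefs <- stats::setNames(rep(0, d), colnames(x))
  inf <- ds$truth$informative
  # oracle model on the observed scale: weight / measure scale
  coefs[inf$feature_id] <- inf$weight / 0.08
  list(
    ds = ds, tbl = tbl,
    model = linear_oracle_model(coefs, colnames(x)),
    informative = inf$feature_id,
    split = make_split(n, seed = seed)
  )
}

test_that("inclusion counts are conserved and bounded", {
  su <- make_linear_setup()
  imp <- permutation_importance(su$model, su$tbl, su$ds$scores, su$split,
                                group_size = 6, n_permutations = 150, seed = 2)
  expect_equal(sum(imp$n_included), 6 * 150)
  expect_true(all(imp$n_included >= 0))
  g <- glance(imp)
  expect_equal(g$group_size, 6L)
  expect_equal(g$n_permutations, 150L)
})

test_that("group_size = d includes every feature in every permutation", {
  su <- make_linear_setup(n = 120, d = 12, k = 3, seed = 3)
  imp <- permutation_importance(su$model, su$tbl, su$ds$scores, su$split,
                                group_size = 12, n_permutations = 40, seed = 1)
  expect_equal(imp$n_included, rep(40L, 12))
})

test_that("a constant column is unchanged by shuffling and contributes zero", {
  su <- make_linear_setup(n = 200, d = 15, k = 3, seed = 5)
  tbl <- su$tbl
  tbl[[2]] <- 1 # first feature constant
  # single-feature groups isolate each feature's own effect: shuffling a
  # constant column leaves the matrix (and hence r) exactly unchanged
  imp <- permutation_importance(su$model, tbl, su$ds$scores, su$split,
                                group_size = 1, n_permutations = 600, seed = 4)
  const_score <- imp$score[imp$feature_id == names(tbl)[2]]
  expect_equal(const_score, 0)
})

test_that("informative features outscore null features on planted signal", {
  hits <- vapply(1:3, function(s) {
    su <- make_linear_setup(n = 400, d = 100, k = 10, seed = 40 + s)
    imp <- permutation_importance(su$model, su$tbl, su$ds$scores, su$split,
                                  group_size = 10, n_permutations = 2000,
                                  seed = s)
    inf <- imp$feature_id %in% su$informative
    expect_gt(mean(imp$score[inf]), mean(imp$score[!inf]))
    pw <- stats::wilcox.test(imp$score[inf], imp$score[!inf],
                             alternative = "greater")$p.value
    expect_lt(pw, 0.01)
    sum(top_features(imp, 10)$feature_id %in% su$informative)
  }, numeric(1))
  expect_true(all(hits >= 7))
})

test_that("single-feature groups agree with classical permutation importance", {
  su <- make_linear_setup(n = 500, d = 8, k = 3, seed = 6)
  y <- su$ds$scores$score
  x <- as.matrix(su$tbl[-1])
  test_idx <- su$split$test
  baseline <- pearson_r(y[test_idx], predict(su$model, x[test_idx, , drop = FALSE]))
  # direct classical implementation, averaging over repeats per feature
  classical <- withr::with_seed(11, vapply(colnames(x), function(j) {
    mean(vapply(1:400, function(rep) {
      xp <- x[test_idx, , drop = FALSE]
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      baseline - pearson_r(y[test_idx], predict(su$model, xp))
    }, numeric(1)))
  }, numeric(1)))
  imp <- permutation_importance(su$model, su$tbl, su$ds$scores, su$split,
                                group_size = 1, n_permutations = 3200, seed = 12)
  got <- stats::setNames(imp$score, imp$feature_id)[names(classical)]
  expect_lt(max(abs(got - classical)), 0.02) # within Monte-Carlo error
})

test_that("retrain mode refits per permutation and records decreases", {
  ds <- small_linear_dataset(n = 150, d = 8, k = 3, noise_sd = 0.2, seed = 8)
  sp <- make_split(150, seed = 2)
  model <- scr_fit(ds$tables[[1]], ds$scores, sp, pretrain_batch = 64,
                   hidden_dim = 16, max_epochs = 4, seed = 3)
  imp <- suppressWarnings( # 3 permutations cannot cover all 8 features
    permutation_importance(model, ds$tables[[1]], ds$scores, sp,
                           group_size = 4, n_permutations = 3,
                           mode = "retrain", seed = 5)
  )
  expect_equal(sum(imp$n_included), 12)
  expect_equal(attr(imp, "mode"), "retrain")
  expect_true(all(is.finite(imp$score[imp$n_included > 0])))
})

test_that("never-sampled features are flagged and score NA", {
  su <- make_linear_setup(n = 120, d = 20, k = 3, seed = 9)
  expect_warning(
    imp <- permutation_importance(su$model, su$tbl, su$ds$scores, su$split,
                                  group_size = 2, n_permutations = 3, seed = 1),
    "never included"
  )
  expect_true(any(is.na(imp$score)))
  expect_equal(length(attr(imp, "unsampled")), sum(is.na(imp$score)))
})

test_that("top_features ranks by score with deterministic id tie-breaks", {
  imp <- tibble::tibble(
    feature_id = c("c_b", "c_a", "c_d", "c_c"),
    score = c(0.5, 0.5, 0.9, NA),
    n_included = c(5L, 5L, 5L, 0L)
  )
  class(imp) <- c("scr_importance", class(imp))
  top <- top_features(imp, 3)
  expect_equal(top$feature_id, c("c_d", "c_a", "c_b")) # ties by id
  full <- top_features(imp, 4)
  expect_equal(sort(full$feature_id), sort(imp$feature_id))
  expect_error(top_features(imp, 0), "positive")
  expect_error(top_features(imp, 9), "exceeds")
})

test_that("category aggregation counts and percentages are conserved", {
  cmap <- tibble::tibble(
    feature_id = sprintf("c%02d", 1:50),
    category = rep(c("association", "projection", "commissural",
                     "cerebellar", "superficial"), each = 10)
  )
  top <- sprintf("c%02d", c(1:8, 11:25, 21:24 + 10, 41:50, 31:33))
  agg <- aggregate_by_category(top, cmap)
  expect_equal(sum(agg$n), length(top))
  expect_equal(sum(agg$pct), 100, tolerance = 1e-9)
  one_cat <- aggregate_by_category(sprintf("c%02d", 1:10), cmap)
  expect_equal(one_cat$n[one_cat$category == "association"], 10)
  expect_equal(one_cat$pct[one_cat$category == "association"], 100)
  expect_equal(sum(one_cat$n), 10)
  expect_error(aggregate_by_category(c("c01", "zz"), cmap), "unmapped")
})

test_that("counts convert to the published percentage pattern", {
  cmap <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:50),
    category = rep(c("association", "projection", "commissural",
                     "cerebellar", "superficial"), times = c(8, 15, 10, 5, 12))
  )
  agg <- aggregate_by_category(cmap$feature_id, cmap)
  expect_equal(
    stats::setNames(agg$pct, agg$category)[c("association", "projection",
                                             "commissural", "cerebellar",
                                             "superficial")],
    c(association = 16, projection = 30, commissural = 20,
      cerebellar = 10, superficial = 24)
  )
})
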