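#' Grouped permutation feature importance
#'
#' Classical permutation importance shuffles one feature at a time, but with
#' ~1000 correlated input features the accuracy drop from a single shuffled
#' column is negligible. This grouped variant instead draws a random group of
#' `group_size` features per permutation (default 10% of the features),
#' shuffles each selected feature's values independently across subjects,
#' records the decrease in test-set Pearson r together with the selected
#' indices, and repeats many times. A feature's importance score is the mean
#' accuracy decrease over all permutations that included it.
#'
#' Two modes are provided. `"retrain"` shuffles the selected features in the
#' *training* rows and refits the model before evaluating on the untouched
#' test set — the full protocol, at one model fit per permutation.
#' `"test_permute"` shuffles the test rows of a single fitted model — a cheap
#' surrogate suitable for large permutation counts; it measures reliance of
#' the fixed model on the features rather than their value for refitting.
#'
#' @param object A fitted model with a `predict` method (used directly in
#'   `test_permute` mode and as the baseline in both modes).
#' @param features Feature table tibble covering all subjects.
#' @param scores Score tibble or aligned numeric vector.
#' @param split The [make_split()] giving the evaluation rows.
#' @param group_size Number of features shuffled jointly per permutation;
#'   default 10% of the features (rounded, at least 1).
#' @param n_permutations Number of random groups drawn (default 1000; large
#'   studies use tens of thousands).
#' @param mode `"test_permute"` (default) or `"retrain"`.
#' @param seed Integer seed for group draws and shuffles.
#' @param refit For `"retrain"` mode: `function(features, scores, split)`
#'   returning a fitted model; defaults to refitting with [scr_fit()] using
#'   the configuration stored on `object` when available.
#' @return A tibble of class `scr_importance` with columns `feature_id`,
#'   `score` (mean decrease in Pearson r; `NA` for never-sampled features) and
#'   `n_included`, plus attributes `baseline_r`, `group_size`,
#'   `n_permutations`, `mode` and `unsampled`.
#' @export
permutation_importance <- function(object, features, scores, split,
                                   group_size = NULL, n_permutations = 1000,
                                   mode = c("test_permute", "retrain"),
                                   seed = 1, refit = NULL) {
  mode <- match.arg(mode)
  x <- feature_matrix(features)
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  d <- ncol(x)
  if (is.null(group_size)) group_size <- max(1L, round(0.1 * d))
  if (group_size < 1 || group_size > d) abort("group_size must be in [1, d]")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  test_idx <- split$test
  x_test <- x[test_idx, , drop = FALSE]
  y_test <- y[test_idx]
  baseline_r <- pearson_r(y_test, as.numeric(predict(object, x_test)))
  score_sum <- numeric(d)
  count <- integer(d)
  n_test <- nrow(x_test)
  withr::with_seed(as.integer(seed), {
    if (mode == "test_permute") {
      for (p in seq_len(n_permutations)) {
        sel <- sample.int(d, group_size)
        saved <- x_test[, sel, drop = FALSE]
        for (j in seq_along(sel)) {
          x_test[, sel[j]] <- x_test[sample.int(n_test), sel[j]]
        }
        r_p <- pearson_r(y_test, as.numeric(predict(object, x_test)))
        x_test[, sel] <- saved
        dr <- baseline_r - r_p
        score_sum[sel] <- score_sum[sel] + dr
        count[sel] <- count[sel] + 1L
      }
    } else {
      if (is.null(refit)) refit <- default_refit(object)
      n_train <- length(split$train)
      for (p in seq_len(n_permutations)) {
        sel <- sample.int(d, group_size)
        x_perm <- x
        for (j in seq_along(sel)) {
          x_perm[split$train, sel[j]] <-
            x_perm[split$train[sample.int(n_train)], sel[j]]
        }
        tbl_perm <- features
        tbl_perm[-1] <- as.data.frame(x_perm)
        model_p <- refit(tbl_perm, scores, split)
        r_p <- pearson_r(y_test, as.numeric(predict(model_p, x_test)))
        dr <- baseline_r - r_p
        score_sum[sel] <- score_sum[sel] + dr
        count[sel] <- count[sel] + 1L
      }
    }
  })
  unsampled <- colnames(x)[count == 0L]
  if (length(unsampled) > 0) {
    warn(sprintf(
      "%d feature(s) were never included in any permutation; their scores are NA",
      length(unsampled)
    ))
  }
  out <- tibble::tibble(
    feature_id = colnames(x),
    score = ifelse(count > 0L, score_sum / pmax(count, 1L), NA_real_),
    n_included = count
  )
  attr(out, "baseline_r") <- baseline_r
  attr(out, "group_size") <- as.integer(group_size)
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "mode") <- mode
  attr(out, "unsampled") <- unsampled
  class(out) <- c("scr_importance", class(out))
  out
}

# Rebuild a model of the same class/configuration for retrain-mode importance.
default_refit <- function(object) {
  if (inherits(object, "scr_model")) {
    cfg <- object$config
    function(features, scores, split) {
      scr_fit(
        features, scores, split,
        theta = cfg$theta, temperature = cfg$temperature,
        corruption = cfg$corruption, pretrain_batch = cfg$pretrain_batch,
        finetune_batch = cfg$finetune_batch, learning_rate = cfg$learning_rate,
        hidden_dim = cfg$hidden_dim, patience = cfg$patience,
        max_epochs = cfg$max_epochs, seed = cfg$seed
      )
    }
  } else if (inherits(object, "mlp_model")) {
    function(features, scores, split) mlp_fit(features, scores, split)
  } else {
    abort("supply `refit` for retrain-mode importance with this model class")
  }
}

#' Top-ranked features by importance
#'
#' @param result An [permutation_importance()] result.
#' @param k Number of features to return (e.g., 50 for the most predictive
#'   fiber clusters).
#' @return The `k` highest-scoring rows, sorted by descending score with ties
#'   broken by `feature_id`; never-sampled features rank last.
#' @export
top_features <- function(result, k) {
  if (k <= 0) abort("k must be positive")
  if (k > nrow(result)) abort("k exceeds the number of features")
  dplyr::slice_head(
    dplyr::arrange(tibble::as_tibble(result), dplyr::desc(.data$score), .data$feature_id),
    n = k
  )
}

#' Aggregate top features by anatomical category
#'
#' Counts how many of the selected features fall in each anatomical tract
#' category (association, projection, commissural, cerebellar, superficial),
#' with percentages of the selection size.
#'
#' @param top A [top_features()] tibble or character vector of feature ids.
#' @param category_map Tibble with columns `feature_id`, `category` covering
#'   every selected feature.
#' @return A tibble with one row per category present in the map: `category`,
#'   `n`, `pct` (percentages sum to 100 up to rounding).
#' @export
aggregate_by_category <- function(top, category_map) {
  ids <- if (is.character(top)) top else top$feature_id
  idx <- match(ids, category_map$feature_id)
  if (anyNA(idx)) {
    abort(paste0(
      "unmapped feature(s): ",
      paste(head(ids[is.na(idx)], 5), collapse = ", ")
    ))
  }
  cats <- sort(unique(category_map$category))
  counts <- table(factor(category_map$category[idx], levels = cats))
  tibble::tibble(
    category = cats,
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / length(ids)
  )
}
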