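#' Pearson correlation between truth and prediction
#'
#' The accuracy metric for score prediction: the product-moment correlation
#' between ground-truth and predicted scores. Undefined for constant vectors,
#' which raise an error rather than returning `NA`.
#'
#' @param truth,pred Numeric vectors of equal length (at least 3).
#' @return A single number in \[-1, 1\].
#' @export
pearson_r <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("truth and pred must have equal length")
  if (length(truth) < 3) abort("need at least 3 observations")
  if (!all(is.finite(truth)) || !all(is.finite(pred))) abort("inputs must be finite")
  if (sd(truth) == 0 || sd(pred) == 0) {
    abort("Pearson r is undefined for a constant vector")
  }
  stats::cor(truth, pred)
}

#' Repeated-split evaluation protocol
#'
#' Repeats an experiment over several independent 70/10/20 train/validation/
#' test splits and records the test-set Pearson r of each repetition. Split
#' seeds are derived deterministically from `seed` alone, so different methods
#' evaluated with the same `seed` (and `n_splits`) see identical splits and
#' their per-split values can be compared pairwise.
#'
#' @param features Feature table tibble.
#' @param scores Score tibble or aligned numeric vector.
#' @param fit_fun A method factory: `function(features, scores, split, seed)`
#'   returning either a fitted model with a `predict` method or a numeric
#'   vector of predictions for the test rows.
#' @param n_splits Number of repetitions (default 10).
#' @param seed Base seed; split `s` uses seed `seed * 1000 + s`.
#' @param fractions Train/validation/test fractions, default `c(0.7, 0.1, 0.2)`.
#' @param method Label stored with the result.
#' @return A tibble of class `scr_eval` with columns `split`, `seed`, `r`.
#' @export
repeated_experiment <- function(features, scores, fit_fun, n_splits = 10,
                                seed = 1, fractions = c(0.7, 0.1, 0.2),
                                method = "model") {
  x_n <- nrow(features)
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  rs <- purrr::map_dbl(seq_len(n_splits), function(s) {
    split_seed <- as.integer(seed) * 1000L + s
    split <- make_split(x_n, fractions, seed = split_seed)
    fit <- fit_fun(features, scores, split, split_seed)
    pred <- if (is.numeric(fit)) fit else {
      as.numeric(predict(fit, features[split$test, , drop = FALSE]))
    }
    if (length(pred) != length(split$test)) {
      abort("fit_fun must yield one prediction per test subject")
    }
    pearson_r(y[split$test], pred)
  })
  out <- tibble::tibble(
    split = seq_len(n_splits),
    seed = as.integer(seed) * 1000L + seq_len(n_splits),
    r = rs
  )
  attr(out, "method") <- method
  class(out) <- c("scr_eval", class(out))
  out
}

#' Paired comparison of per-split accuracies
#'
#' Two-sided paired Student's t-test on split-wise Pearson-r differences
#' between two methods evaluated on identical splits.
#'
#' @param a,b Numeric vectors of per-split r values (or `scr_eval` tibbles),
#'   aligned by split.
#' @return A one-row tibble: `mean_diff`, `statistic`, `df`, `p_value`.
#' @export
paired_comparison <- function(a, b) {
  av <- if (is.data.frame(a)) a$r else a
  bv <- if (is.data.frame(b)) b$r else b
  if (length(av) != length(bv)) abort("per-split vectors must be aligned")
  if (length(av) < 2) abort("need at least 2 splits")
  d <- av - bv
  if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (max(abs(d)) < 1e-10) {
      # identical vectors: no difference at all, t = 0 by convention
      return(tibble::tibble(
        mean_diff = 0, statistic = 0,
        df = length(d) - 1, p_value = 1
      ))
    }
    abort("degenerate paired comparison: constant nonzero split-wise differences")
  }
  tt <- stats::t.test(av, bv, paired = TRUE)
  tibble::tibble(
    mean_diff = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Repeated-measures ANOVA across methods
#'
#' Omnibus one-way within-subject (split) analysis of variance over three or
#' more methods evaluated on identical splits, preceding pairwise paired
#' t-tests. No sphericity correction is applied.
#'
#' @param results Named list of per-split r vectors (or `scr_eval` tibbles),
#'   all aligned on the same splits.
#' @return A one-row tibble: `df_method`, `df_error`, `statistic`, `p_value`.
#' @export
methods_anova <- function(results) {
  if (length(results) < 3) abort("need at least 3 methods for the omnibus test")
  vals <- lapply(results, function(x) if (is.data.frame(x)) x$r else x)
  n <- unique(lengths(vals))
  if (length(n) != 1) abort("methods must share the same number of splits")
  long <- tibble::tibble(
    method = factor(rep(names(results), each = n)),
    split = factor(rep(seq_len(n), times = length(results))),
    r = unlist(vals, use.names = FALSE)
  )
  fit <- stats::aov(r ~ method + Error(split), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  tibble::tibble(
    df_method = tab["method", "Df"],
    df_error = tab["Residuals", "Df"],
    statistic = tab["method", "F value"],
    p_value = tab["method", "Pr(>F)"]
  )
}
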