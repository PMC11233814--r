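#' Make a train/validation/test split
#'
#' Partitions `1:n` into disjoint train, validation and test index sets at the
#' given fractions (default 70/10/20), deterministically for a given seed.
#' Validation and test sizes are floored; the remainder goes to train, so the
#' three sets always form an exact partition.
#'
#' @param n Number of subjects (must allow at least one subject per set).
#' @param fractions Length-3 numeric summing to 1: train, validation, test.
#' @param seed Integer seed controlling the random assignment.
#' @return An object of class `split_spec`: a list with integer vectors
#'   `train`, `val`, `test` plus the `fractions` and `seed` used.
#' @examples
#' sp <- make_split(100, seed = 1)
#' lengths(sp[c("train", "val", "test")])
#' @export
make_split <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be three numbers summing to 1")
  }
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1) {
    abort("n too small to give every split at least one subject")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  out <- list(
    train = sort(perm[seq_len(n_train)]),
    val = sort(perm[n_train + seq_len(n_val)]),
    test = sort(perm[n_train + n_val + seq_len(n_test)]),
    fractions = fractions,
    seed = as.integer(seed)
  )
  class(out) <- "split_spec"
  out
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> train %d / val %d / test %d (seed %d)\n",
    length(x$train), length(x$val), length(x$test), x$seed
  ))
  invisible(x)
}

#' Fit a per-feature standardizer on training rows
#'
#' Computes per-feature mean and standard deviation on the training rows only,
#' so no information leaks from validation or test subjects into the
#' preprocessing. Features with zero training variance get scale 1 (they map
#' to exactly 0 after centering). FA (~0-1), MD (~1e-3 mm^2/s) and streamline
#' counts live on incompatible scales; z-scoring puts them on a common one
#' before model fitting and makes corruption draws scale-consistent.
#'
#' @param table A feature table tibble (or bare numeric matrix).
#' @param train_idx Integer row indices of the training subjects.
#' @return An object of class `standardizer` holding `center` and `scale`
#'   vectors named by feature.
#' @export
fit_standardizer <- function(table, train_idx) {
  x <- if (is.matrix(table)) table else feature_matrix(table)
  if (length(train_idx) < 1) abort("train_idx must be non-empty")
  xt <- x[train_idx, , drop = FALSE]
  center <- colMeans(xt)
  # population standard deviation, so a two-value column {0, 2} maps to {-1, +1}
  scale <- sqrt(colMeans(sweep(xt, 2, center)^2))
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' Apply or invert a standardizer
#'
#' @param standardizer A fitted [fit_standardizer()] object.
#' @param table Feature table tibble or numeric matrix with the same features.
#' @return A numeric matrix of z-scored (or back-transformed) values.
#' @export
standardize <- function(standardizer, table) {
  x <- if (is.matrix(table)) table else feature_matrix(table)
  if (ncol(x) != length(standardizer$center)) {
    abort("feature count does not match the standardizer")
  }
  sweep(sweep(x, 2, standardizer$center), 2, standardizer$scale, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(standardizer, table) {
  x <- if (is.matrix(table)) table else feature_matrix(table)
  sweep(sweep(x, 2, standardizer$scale, "*"), 2, standardizer$center, "+")
}
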