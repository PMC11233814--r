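# Small in-code fixtures shared across test files.

tiny_feature_table <- function(n = 6, d = 4, seed = 1, measure = "FA") {
  withr::with_seed(seed, {
    as_feature_table(
      tibble::tibble(
        subject_id = sprintf("s%02d", seq_len(n)),
        !!!stats::setNames(
          lapply(seq_len(d), function(j) rnorm(n)),
          sprintf("cluster_%03d", seq_len(d))
        )
      ),
      measure_name = measure
    )
  })
}

small_linear_dataset <- function(n = 400, d = 20, k = 4, noise_sd = 0, seed = 1) {
  generate_dataset(synthetic_spec(
    n, n_features = d, n_informative = k, n_measures = 1,
    noise_sd = noise_sd, zero_inflation = 0, seed = seed
  ))
}

# A transparent linear "model" with a predict method, for exercising the
# importance and ensemble machinery without neural-network training time.
linear_oracle_model <- function(coefs, feature_ids) {
  structure(
    list(coefs = coefs, feature_ids = feature_ids),
    class = "test_linear_model"
  )
}

predict.test_linear_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else as.matrix(newdata[-1])
  drop(x[, object$feature_ids, drop = FALSE] %*% object$coefs)
}

# Constant-output stub model for ensemble arithmetic checks.
constant_model <- function(value, measure) {
  structure(list(value = value, measure_name = measure), class = "test_const_model")
}

predict.test_const_model <- function(object, newdata, ...) {
  ids <- if (is.matrix(newdata)) rownames(newdata) else newdata$subject_id
  stats::setNames(rep(object$value, length(ids)), ids)
}

# Register the S3 methods inside the test runner session.
registerS3method("predict", "test_linear_model", predict.test_linear_model,
                 envir = asNamespace("stats"))
registerS3method("predict", "test_const_model", predict.test_const_model,
                 envir = asNamespace("stats"))
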