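#' Tidy the training history of a fitted model
#'
#' @param x An `scr_model` or `mlp_model`.
#' @param ... Unused.
#' @return A tibble with columns `phase`, `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.scr_model <- function(x, ...) {
  dplyr::select(x$history, "phase", "epoch", "train_loss", "val_loss")
}

#' @rdname tidy.scr_model
#' @export
tidy.mlp_model <- tidy.scr_model

#' One-row summary of a fitted model
#'
#' @param x An `scr_model`.
#' @param ... Unused.
#' @return A one-row tibble of the key hyperparameters and the best epochs /
#'   validation losses of both phases.
#' @export
glance.scr_model <- function(x, ...) {
  h <- x$history
  best_val <- function(ph) {
    hp <- h[h$phase == ph, ]
    if (nrow(hp) == 0) NA_real_ else min(hp$val_loss)
  }
  tibble::tibble(
    measure = x$measure_name %||% NA_character_,
    n_features = length(x$feature_ids),
    hidden_dim = x$config$hidden_dim,
    theta = x$config$theta,
    temperature = x$config$temperature,
    corruption = x$config$corruption,
    pretrain_epochs = sum(h$phase == "contrastive"),
    pretrain_best_val = best_val("contrastive"),
    finetune_epochs = sum(h$phase == "finetune"),
    finetune_best_val = best_val("finetune")
  )
}

#' @export
glance.mlp_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    measure = x$measure_name %||% NA_character_,
    n_features = length(x$feature_ids),
    epochs = nrow(h),
    best_val_mse = min(h$val_loss)
  )
}

#' Tidy an importance result
#'
#' @param x An [permutation_importance()] result.
#' @param ... Unused.
#' @return The per-feature tibble sorted by descending score.
#' @export
tidy.scr_importance <- function(x, ...) {
  dplyr::arrange(tibble::as_tibble(x), dplyr::desc(.data$score), .data$feature_id)
}

#' @export
glance.scr_importance <- function(x, ...) {
  tibble::tibble(
    baseline_r = attr(x, "baseline_r"),
    group_size = attr(x, "group_size"),
    n_permutations = attr(x, "n_permutations"),
    mode = attr(x, "mode"),
    n_unsampled = length(attr(x, "unsampled"))
  )
}

#' Summarize a repeated-split evaluation
#'
#' @param x A [repeated_experiment()] result.
#' @param ... Unused.
#' @return One row: method label, number of splits, mean and standard
#'   deviation of the per-split Pearson r.
#' @export
glance.scr_eval <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method") %||% "model",
    n_splits = nrow(x),
    mean_r = mean(x$r),
    sd_r = sd(x$r)
  )
}
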