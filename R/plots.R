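#' Plot training history
#'
#' Per-epoch training and validation loss of the contrastive and fine-tuning
#' phases (each on its own panel; the two losses are on different scales).
#'
#' @param object An `scr_model` or `mlp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scr_model <- function(object, ...) {
  hist <- tidy(object) |>
    tidyr::pivot_longer(
      c("train_loss", "val_loss"),
      names_to = "set", values_to = "loss"
    ) |>
    dplyr::mutate(set = sub("_loss$", "", .data$set))
  ggplot2::ggplot(hist, ggplot2::aes(.data$epoch, .data$loss, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scr_model
#' @export
autoplot.mlp_model <- autoplot.scr_model

#' Plot top feature importances
#'
#' @param object An [permutation_importance()] result.
#' @param k Number of top features to show (default 25).
#' @param category_map Optional feature-to-category map used to colour bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scr_importance <- function(object, k = 25, category_map = NULL, ...) {
  top <- top_features(object, min(k, nrow(object)))
  top$feature_id <- factor(top$feature_id, levels = rev(top$feature_id))
  p <- if (is.null(category_map)) {
    ggplot2::ggplot(top, ggplot2::aes(.data$score, .data$feature_id))
  } else {
    top$category <- category_map$category[match(top$feature_id, category_map$feature_id)]
    ggplot2::ggplot(
      top, ggplot2::aes(.data$score, .data$feature_id, fill = .data$category)
    )
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "mean decrease in Pearson r", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-split evaluation results
#'
#' Dot plot of per-split Pearson r with the mean marked, facilitating visual
#' comparison of methods evaluated on shared splits.
#'
#' @param object A [repeated_experiment()] result, or a named list of them.
#' @param ... Further `scr_eval` objects to overlay.
#' @return A ggplot object.
#' @export
autoplot.scr_eval <- function(object, ...) {
  extra <- list(...)
  evals <- c(list(object), extra[vapply(extra, inherits, logical(1), "scr_eval")])
  long <- dplyr::bind_rows(lapply(evals, function(e) {
    tibble::tibble(
      method = attr(e, "method") %||% "model",
      split = e$split, r = e$r
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$r)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$split)), show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "test Pearson r") +
    ggplot2::theme_minimal()
}
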