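#' Positive/negative pair mask from continuous labels
#'
#' In supervised contrastive learning for classification, two samples are a
#' positive pair when they share a class label. With continuous regression
#' labels that rule is replaced by a threshold on the absolute label
#' difference: samples `i` and `j` (`i != j`) are a positive pair exactly when
#' `|y_i - y_j| < theta` (strict inequality; a difference equal to `theta` is
#' negative). A corrupted copy keeps its source row's label, so an original
#' and its augmented twin are always a positive pair.
#'
#' @param labels Numeric vector of the labels of every sample in the combined
#'   batch (originals followed by corrupted copies), length `M >= 2`.
#' @param theta Positive label-difference threshold. The default 0.35 suits
#'   component scores spanning roughly \[-3, 3\]; performance is robust for
#'   theta in about 0.1-0.5.
#' @return An `M x M` logical matrix of class `pair_mask`: symmetric, `FALSE`
#'   on the diagonal, with attributes `labels` and `theta`.
#' @examples
#' build_pair_mask(c(0, 0.2, 1), theta = 0.35)
#' @export
build_pair_mask <- function(labels, theta = 0.35) {
  if (!is.numeric(labels) || length(labels) < 2) {
    abort("labels must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(labels))) abort("labels must be finite")
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    abort("theta must be a single positive number")
  }
  mask <- abs(outer(labels, labels, "-")) < theta
  diag(mask) <- FALSE
  structure(mask, labels = labels, theta = theta, class = c("pair_mask", "matrix"))
}
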