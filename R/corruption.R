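#' Random feature corruption of a mini-batch
#'
#' Tabular data augmentation for contrastive pretraining: for every row, a
#' uniformly random subset of `round(rate * d)` feature positions is selected
#' (independently per row), and each selected entry is overwritten with the
#' value in the same column of a uniformly random *other* row of the batch.
#' Corrupted copies keep the label of the row they came from, so column
#' marginals are preserved while row-level structure is broken.
#'
#' @param batch Numeric matrix, rows are samples in the mini-batch.
#' @param rate Corruption rate `c` in \[0, 1\]: the fraction of features
#'   replaced per row. Default 0.5.
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the ambient RNG state is untouched.
#' @return A numeric matrix of the same shape as `batch`.
#' @examples
#' x <- matrix(1:12, nrow = 3)
#' corrupt_batch(x, rate = 0.5, seed = 7)
#' @export
corrupt_batch <- function(batch, rate = 0.5, seed = NULL) {
  if (!is.matrix(batch) || !is.numeric(batch)) abort("batch must be a numeric matrix")
  if (rate < 0 || rate > 1) abort("corruption rate must be in [0, 1]")
  if (rate == 0) return(batch)
  m <- nrow(batch)
  d <- ncol(batch)
  if (m < 2) abort("need at least 2 rows to draw replacement values from other samples")
  k <- round(rate * d)
  if (k == 0) return(batch)
  draw <- function() {
    out <- batch
    for (i in seq_len(m)) {
      sel <- sample.int(d, k)
      # donor rows drawn uniformly among rows != i, one per selected position
      donors <- sample.int(m - 1L, k, replace = TRUE)
      donors <- donors + (donors >= i)
      out[i, sel] <- batch[cbind(donors, sel)]
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
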