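#' Supervised contrastive loss over normalized embeddings
#'
#' Computes the supervised contrastive loss
#' \deqn{L = \sum_{r \in R} \frac{-1}{|P(r)|} \sum_{p \in P(r)}
#'   \log \frac{\exp(z_r \cdot z_p / \tau)}{\sum_{a \in A(r)} \exp(z_r \cdot z_a / \tau)},}
#' where `R` is the combined batch (originals plus corrupted copies), `P(r)`
#' the positive set of anchor `r` given by the pair mask, and
#' `A(r) = R \ {r}`. Anchors with an empty positive set contribute 0. Because
#' every positive's term also appears in the denominator, each summand is the
#' negative log of a ratio at most 1, so the loss is nonnegative. The sum runs
#' over anchors (not the mean); set `average = TRUE` for a batch-size
#' independent value when logging.
#'
#' Log-sum-exp stabilization (subtracting each anchor's maximum logit) is
#' applied; it leaves the value unchanged analytically.
#'
#' @param embeddings Numeric `M x e` matrix of embeddings with unit Euclidean
#'   row norms (checked to 1e-6).
#' @param mask A [build_pair_mask()] result (or logical `M x M` matrix,
#'   symmetric with `FALSE` diagonal).
#' @param temperature Positive temperature `tau` dividing the dot products;
#'   default 1.
#' @param average If `TRUE`, divide the total by the number of anchors.
#' @return A single nonnegative finite number.
#' @examples
#' z <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
#' m <- build_pair_mask(c(0, 0), theta = 0.35)
#' supcon_loss(z, m) # identical embeddings, mutual positives -> 0
#' @export
supcon_loss <- function(embeddings, mask, temperature = 1, average = FALSE) {
  res <- supcon_loss_grad(embeddings, mask, temperature, want_grad = FALSE)
  if (average) res$loss / nrow(embeddings) else res$loss
}

# Loss and (optionally) its gradient with respect to the embeddings.
# Shared by the public loss function and the pretraining loop.
supcon_loss_grad <- function(embeddings, mask, temperature = 1, want_grad = TRUE) {
  z <- embeddings
  if (!is.matrix(z) || !is.numeric(z)) abort("embeddings must be a numeric matrix")
  m <- nrow(z)
  if (!is.logical(mask) && !inherits(mask, "pair_mask")) {
    abort("mask must be a logical pair mask")
  }
  if (nrow(mask) != m || ncol(mask) != m) {
    abort("mask dimension does not match the number of embeddings")
  }
  if (temperature <= 0) abort("temperature must be positive")
  norms <- sqrt(rowSums(z^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("embeddings must be L2-normalized (unit row norms)")
  }
  pos <- unclass(mask)
  logits <- tcrossprod(z) / temperature
  diag(logits) <- -Inf # anchor excluded from A(r)
  mx <- apply(logits, 1, max)
  w <- exp(logits - mx)
  denom <- rowSums(w)
  log_denom <- log(denom) + mx
  n_pos <- rowSums(pos)
  has_pos <- n_pos > 0
  # per-anchor loss: mean over positives of (log_denom - logit)
  per_anchor <- numeric(m)
  if (any(has_pos)) {
    masked <- logits
    masked[!pos] <- 0
    pos_logit_sum <- rowSums(masked)
    per_anchor[has_pos] <-
      log_denom[has_pos] - pos_logit_sum[has_pos] / n_pos[has_pos]
  }
  loss <- sum(per_anchor)
  if (!is.finite(loss)) abort("contrastive loss diverged (non-finite)")
  if (!want_grad) {
    return(list(loss = loss, grad = NULL))
  }
  # dL/d(dot_ra) = (softmax_ra - pos_ra / n_pos_r) / temperature for anchors
  # with positives; softmax over A(r) only (diagonal weight is 0 by -Inf).
  q <- w / denom
  g <- q
  g[pos] <- g[pos] - (1 / n_pos[row(pos)])[pos]
  g[!has_pos, ] <- 0
  g <- g / temperature
  grad <- (g + t(g)) %*% z
  list(loss = loss, grad = grad)
}

# Project an embedding-space gradient through row-wise L2 normalization:
# z = u / ||u||; returns gradient with respect to the unnormalized rows u.
l2norm_backward <- function(u, z, grad_z) {
  norms <- sqrt(rowSums(u^2))
  (grad_z - rowSums(grad_z * z) * z) / norms
}

l2_normalize_rows <- function(u) {
  u / sqrt(rowSums(u^2))
}
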