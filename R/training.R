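# Two-phase training: contrastive pretraining of the encoder + projector,
# then frozen-encoder fine-tuning of a regression head with MSE.

batch_chunks <- function(order, size) {
  split(order, ceiling(seq_along(order) / size))
}

# Contrastive pretraining. x_* are standardized matrices; draws from the
# ambient RNG except the validation corruption, which uses a fixed seed so the
# early-stopping criterion compares identical validation batches every epoch.
scr_pretrain <- function(x_train, y_train, x_val, y_val, cfg) {
  d <- ncol(x_train)
  h <- cfg$hidden_dim
  enc <- mlp_init(c(d, h, h, h, h), relu = rep(TRUE, 4))
  proj <- mlp_init(c(h, h, h), relu = c(TRUE, FALSE))
  opt_enc <- adam_init(enc)
  opt_proj <- adam_init(proj)
  stopper <- early_stopper(cfg$patience)
  history <- list()
  n <- nrow(x_train)
  val_cor <- withr::with_seed(
    cfg$val_seed, corrupt_batch(x_val, cfg$corruption)
  )
  contrastive_eval <- function(x, xc, y, enc, proj, want_grad) {
    x2 <- rbind(x, xc)
    f_enc <- mlp_forward(enc, x2, cache = want_grad)
    hid <- if (want_grad) f_enc$out else f_enc
    f_proj <- mlp_forward(proj, hid, cache = want_grad)
    u <- if (want_grad) f_proj$out else f_proj
    z <- l2_normalize_rows(u)
    mask <- build_pair_mask(c(y, y), cfg$theta)
    lg <- supcon_loss_grad(z, mask, cfg$temperature, want_grad = want_grad)
    list(lg = lg, f_enc = f_enc, f_proj = f_proj, u = u, z = z)
  }
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    tr_anchors <- 0L
    for (chunk in batch_chunks(ord, cfg$pretrain_batch)) {
      if (length(chunk) < 2L) next
      xb <- x_train[chunk, , drop = FALSE]
      xc <- corrupt_batch(xb, cfg$corruption)
      ev <- contrastive_eval(xb, xc, y_train[chunk], enc, proj, TRUE)
      g_u <- l2norm_backward(ev$u, ev$z, ev$lg$grad)
      bp_proj <- mlp_backward(proj, ev$f_proj, g_u)
      bp_enc <- mlp_backward(enc, ev$f_enc, bp_proj$g_in)
      st <- adam_step(proj, bp_proj, opt_proj, lr = cfg$learning_rate)
      proj <- st$net; opt_proj <- st$state
      st <- adam_step(enc, bp_enc, opt_enc, lr = cfg$learning_rate)
      enc <- st$net; opt_enc <- st$state
      tr_loss <- tr_loss + ev$lg$loss
      tr_anchors <- tr_anchors + 2L * length(chunk)
    }
    val_loss <- 0
    val_anchors <- 0L
    for (chunk in batch_chunks(seq_len(nrow(x_val)), cfg$pretrain_batch)) {
      if (length(chunk) < 2L) next
      ev <- contrastive_eval(
        x_val[chunk, , drop = FALSE], val_cor[chunk, , drop = FALSE],
        y_val[chunk], enc, proj, FALSE
      )
      val_loss <- val_loss + ev$lg$loss
      val_anchors <- val_anchors + 2L * length(chunk)
    }
    tr_mean <- tr_loss / max(tr_anchors, 1L)
    val_mean <- val_loss / max(val_anchors, 1L)
    history[[epoch]] <- c(epoch = epoch, train_loss = tr_mean, val_loss = val_mean)
    if (isTRUE(cfg$verbose)) {
      message(sprintf("pretrain epoch %d: train %.4f val %.4f", epoch, tr_mean, val_mean))
    }
    if (stopper$update(val_mean, epoch, list(enc = enc, proj = proj))) break
  }
  best <- stopper$best()
  hist <- tibble::as_tibble(do.call(rbind, history))
  list(
    encoder = best$params$enc, projector = best$params$proj,
    history = hist, best_epoch = best$epoch,
    final_encoder = enc, final_projector = proj
  )
}

# Generic mini-batch MSE trainer with Adam and patience-based early stopping.
train_mse <- function(net, x_train, y_train, x_val, y_val, cfg) {
  opt <- adam_init(net)
  stopper <- early_stopper(cfg$patience)
  history <- list()
  n <- nrow(x_train)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    tr_n <- 0L
    for (chunk in batch_chunks(ord, cfg$finetune_batch)) {
      xb <- x_train[chunk, , drop = FALSE]
      fwd <- mlp_forward(net, xb, cache = TRUE)
      resid <- drop(fwd$out) - y_train[chunk]
      m <- length(chunk)
      grad_out <- matrix(2 * resid / m, ncol = 1)
      bp <- mlp_backward(net, fwd, grad_out)
      st <- adam_step(net, bp, opt, lr = cfg$learning_rate)
      net <- st$net; opt <- st$state
      tr_loss <- tr_loss + sum(resid^2)
      tr_n <- tr_n + m
    }
    val_pred <- drop(mlp_forward(net, x_val))
    val_mse <- mean((val_pred - y_val)^2)
    history[[epoch]] <- c(
      epoch = epoch, train_loss = tr_loss / tr_n, val_loss = val_mse
    )
    if (isTRUE(cfg$verbose)) {
      message(sprintf("mse epoch %d: train %.4f val %.4f", epoch, tr_loss / tr_n, val_mse))
    }
    if (stopper$update(val_mse, epoch, net)) break
  }
  best <- stopper$best()
  list(
    net = best$params, history = tibble::as_tibble(do.call(rbind, history)),
    best_epoch = best$epoch
  )
}

#' Contrastive pretraining of the encoder
#'
#' Phase 1 of the supervised contrastive regression procedure, run on its
#' own: z-scores the features with training-split statistics, then trains the
#' four-layer encoder and two-layer projector with the supervised contrastive
#' loss over corrupted-copy-augmented mini-batches, with early stopping on
#' the validation contrastive loss (evaluated under a fixed corruption seed
#' so epochs are compared on identical validation batches). Returns the
#' pretrained encoder ready for [scr_finetune()].
#'
#' @inheritParams scr_fit
#' @return An object of class `scr_encoder` holding the encoder, projector,
#'   standardizer, split, configuration and pretraining history.
#' @export
scr_pretrain_encoder <- function(features, scores, split = NULL,
                                 theta = 0.35, temperature = 1, corruption = 0.5,
                                 pretrain_batch = 2048, finetune_batch = 128,
                                 learning_rate = 0.001, hidden_dim = 256,
                                 patience = 3, max_epochs = 200, seed = 1,
                                 measure_name = attr(features, "measure_name"),
                                 verbose = FALSE) {
  x <- feature_matrix(features)
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  if (length(y) != nrow(x)) abort("scores do not align with the feature table")
  if (is.null(split)) split <- make_split(nrow(x), seed = seed)
  cfg <- list(
    theta = theta, temperature = temperature, corruption = corruption,
    pretrain_batch = pretrain_batch, finetune_batch = finetune_batch,
    learning_rate = learning_rate, hidden_dim = hidden_dim,
    patience = patience, max_epochs = max_epochs, seed = as.integer(seed),
    val_seed = as.integer(seed) + 90001L, verbose = verbose
  )
  std <- fit_standardizer(x, split$train)
  xs <- standardize(std, x)
  pre <- withr::with_seed(cfg$seed, scr_pretrain(
    xs[split$train, , drop = FALSE], y[split$train],
    xs[split$val, , drop = FALSE], y[split$val], cfg
  ))
  structure(
    list(
      encoder = pre$encoder, projector = pre$projector, standardizer = std,
      feature_ids = colnames(x), measure_name = measure_name,
      config = cfg, split = split,
      history = dplyr::mutate(pre$history, phase = "contrastive"),
      best_epoch = pre$best_epoch
    ),
    class = "scr_encoder"
  )
}

#' @export
print.scr_encoder <- function(x, ...) {
  cat(sprintf(
    "<scr_encoder> measure %s: %d features, hidden %d, best epoch %d\n",
    x$measure_name %||% "?", length(x$feature_ids), x$config$hidden_dim,
    x$best_epoch
  ))
  invisible(x)
}

#' Frozen-encoder fine-tuning of the regression head
#'
#' Phase 2: the pretrained encoder is frozen (its parameters are carried into
#' the returned model untouched — bit-identical), the projector is set aside,
#' and a two-layer regression head on the encoder output is trained with mean
#' squared error, Adam, and early stopping on validation MSE.
#'
#' @param pretrained An [scr_pretrain_encoder()] result.
#' @inheritParams scr_fit
#' @return An `scr_model`.
#' @export
scr_finetune <- function(pretrained, features, scores, verbose = FALSE) {
  stopifnot(inherits(pretrained, "scr_encoder"))
  x <- feature_matrix(features)
  if (!identical(colnames(x), pretrained$feature_ids)) {
    abort("feature ids do not match the pretrained encoder")
  }
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  split <- pretrained$split
  cfg <- pretrained$config
  cfg$verbose <- verbose
  xs <- standardize(pretrained$standardizer, x)
  h_train <- mlp_forward(pretrained$encoder, xs[split$train, , drop = FALSE])
  h_val <- mlp_forward(pretrained$encoder, xs[split$val, , drop = FALSE])
  ft <- withr::with_seed(cfg$seed + 1L, {
    reg <- mlp_init(c(cfg$hidden_dim, cfg$hidden_dim, 1L), relu = c(TRUE, FALSE))
    train_mse(reg, h_train, y[split$train], h_val, y[split$val], cfg)
  })
  history <- dplyr::bind_rows(
    pretrained$history,
    dplyr::mutate(ft$history, phase = "finetune")
  )
  structure(
    list(
      encoder = pretrained$encoder, projector = pretrained$projector,
      regressor = ft$net, standardizer = pretrained$standardizer,
      feature_ids = pretrained$feature_ids,
      measure_name = pretrained$measure_name, config = cfg, split = split,
      history = history,
      best_epochs = c(contrastive = pretrained$best_epoch, finetune = ft$best_epoch)
    ),
    class = "scr_model"
  )
}

#' Fit a supervised contrastive regression model
#'
#' Trains one predictor for one measure table in two phases. Phase 1
#' (contrastive pretraining): each shuffled mini-batch is augmented with a
#' randomly feature-corrupted copy, both are embedded through a four-layer
#' encoder and a two-layer projector, embeddings are L2-normalized, positive
#' pairs are determined by `|y_i - y_j| < theta`, and the supervised
#' contrastive loss is minimized with Adam. Phase 2 (fine-tuning): the encoder
#' is frozen, the projector set aside, and a two-layer regression head on top
#' of the encoder output is trained with mean squared error. Both phases use
#' early stopping on a validation loss and keep the best-validation-epoch
#' parameters. Features are z-scored with training-split statistics before
#' both phases; labels are used as-is.
#'
#' @param features Feature table tibble (`subject_id` + numeric columns).
#' @param scores A score tibble (`subject_id`, `score`) or a numeric vector
#'   aligned with the rows of `features`.
#' @param split A [make_split()] object; `NULL` fits a fresh 70/10/20 split
#'   from `seed`.
#' @param theta Label-difference threshold for pair determination (default
#'   0.35, suited to labels spanning roughly \[-3, 3\]).
#' @param temperature Contrastive-loss temperature (default 1).
#' @param corruption Corruption rate for the augmentation (default 0.5).
#' @param pretrain_batch Mini-batch size of the contrastive phase (default
#'   2048; the combined batch with corrupted copies is twice this).
#' @param finetune_batch Mini-batch size of the fine-tuning phase (default 128).
#' @param learning_rate Adam learning rate for both phases (default 0.001).
#' @param hidden_dim Hidden width of all layers (default 256).
#' @param patience Early-stopping patience in epochs (default 3).
#' @param max_epochs Epoch cap for each phase (default 200; early stopping
#'   normally triggers much sooner).
#' @param seed Integer seed controlling every random draw in the fit.
#' @param measure_name Optional measure label stored on the model.
#' @param verbose Print per-epoch losses.
#' @return An object of class `scr_model` with the trained encoder, projector,
#'   regression head, standardizer, configuration and per-epoch history.
#' @seealso [predict.scr_model()], [mlp_fit()], [scr_ensemble()]
#' @export
scr_fit <- function(features, scores, split = NULL,
                    theta = 0.35, temperature = 1, corruption = 0.5,
                    pretrain_batch = 2048, finetune_batch = 128,
                    learning_rate = 0.001, hidden_dim = 256,
                    patience = 3, max_epochs = 200, seed = 1,
                    measure_name = attr(features, "measure_name"),
                    verbose = FALSE) {
  x <- feature_matrix(features)
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  if (length(y) != nrow(x)) abort("scores do not align with the feature table")
  if (is.null(split)) split <- make_split(nrow(x), seed = seed)
  cfg <- list(
    theta = theta, temperature = temperature, corruption = corruption,
    pretrain_batch = pretrain_batch, finetune_batch = finetune_batch,
    learning_rate = learning_rate, hidden_dim = hidden_dim,
    patience = patience, max_epochs = max_epochs, seed = as.integer(seed),
    val_seed = as.integer(seed) + 90001L, verbose = verbose
  )
  std <- fit_standardizer(x, split$train)
  xs <- standardize(std, x)
  withr::with_seed(cfg$seed, {
    pre <- scr_pretrain(
      xs[split$train, , drop = FALSE], y[split$train],
      xs[split$val, , drop = FALSE], y[split$val], cfg
    )
    h_train <- mlp_forward(pre$encoder, xs[split$train, , drop = FALSE])
    h_val <- mlp_forward(pre$encoder, xs[split$val, , drop = FALSE])
    reg <- mlp_init(c(hidden_dim, hidden_dim, 1L), relu = c(TRUE, FALSE))
    ft <- train_mse(reg, h_train, y[split$train], h_val, y[split$val], cfg)
  })
  history <- dplyr::bind_rows(
    dplyr::mutate(pre$history, phase = "contrastive"),
    dplyr::mutate(ft$history, phase = "finetune")
  )
  structure(
    list(
      encoder = pre$encoder, projector = pre$projector, regressor = ft$net,
      standardizer = std, feature_ids = colnames(x),
      measure_name = measure_name, config = cfg, split = split,
      history = history,
      best_epochs = c(contrastive = pre$best_epoch, finetune = ft$best_epoch)
    ),
    class = "scr_model"
  )
}

#' Predict from a fitted supervised contrastive regression model
#'
#' Applies the stored standardizer, the frozen encoder, and the fine-tuned
#' regression head. Deterministic and row-wise.
#'
#' @param object An `scr_model` from [scr_fit()].
#' @param newdata Feature table tibble or bare numeric matrix whose columns
#'   match the training features (same identifiers, same order).
#' @param ... Unused.
#' @return A named numeric vector of predicted scores.
#' @export
predict.scr_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (!identical(colnames(x), object$feature_ids)) {
    abort("feature ids of newdata do not match the model's training features")
  }
  xs <- standardize(object$standardizer, x)
  h <- mlp_forward(object$encoder, xs)
  setNames(drop(mlp_forward(object$regressor, h)), rownames(x))
}

#' @export
print.scr_model <- function(x, ...) {
  cat(sprintf(
    "<scr_model> measure %s: %d features, hidden %d\n  pretrain best epoch %d, finetune best epoch %d\n",
    x$measure_name %||% "?", length(x$feature_ids), x$config$hidden_dim,
    x$best_epochs[["contrastive"]], x$best_epochs[["finetune"]]
  ))
  invisible(x)
}

#' Fit the plain MLP reference regressor
#'
#' A multilayer perceptron with the same architecture as the contrastive model
#' (four encoder layers plus the two-layer regression head) trained end-to-end
#' from scratch with mean squared error — no contrastive pretraining, no
#' augmentation. Serves as the reference against which the contrastive model
#' is compared.
#'
#' @inheritParams scr_fit
#' @param batch Mini-batch size (default 128).
#' @return An object of class `mlp_model` with a [predict][predict.mlp_model]
#'   method.
#' @export
mlp_fit <- function(features, scores, split = NULL, batch = 128,
                    learning_rate = 0.001, hidden_dim = 256,
                    patience = 3, max_epochs = 200, seed = 1,
                    measure_name = attr(features, "measure_name"),
                    verbose = FALSE) {
  x <- feature_matrix(features)
  y <- if (is.numeric(scores)) scores else aligned_scores(features, scores)
  if (is.null(split)) split <- make_split(nrow(x), seed = seed)
  cfg <- list(
    finetune_batch = batch, learning_rate = learning_rate,
    patience = patience, max_epochs = max_epochs, verbose = verbose
  )
  std <- fit_standardizer(x, split$train)
  xs <- standardize(std, x)
  h <- hidden_dim
  withr::with_seed(as.integer(seed), {
    net <- mlp_init(c(ncol(x), h, h, h, h, h, 1L), relu = c(rep(TRUE, 5), FALSE))
    fit <- train_mse(
      net, xs[split$train, , drop = FALSE], y[split$train],
      xs[split$val, , drop = FALSE], y[split$val], cfg
    )
  })
  structure(
    list(
      net = fit$net, standardizer = std, feature_ids = colnames(x),
      measure_name = measure_name, config = cfg, split = split,
      history = dplyr::mutate(fit$history, phase = "mse"),
      best_epochs = c(mse = fit$best_epoch)
    ),
    class = "mlp_model"
  )
}

#' @describeIn mlp_fit Predict from the reference MLP.
#' @param object,newdata,... As in [predict.scr_model()].
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (!identical(colnames(x), object$feature_ids)) {
    abort("feature ids of newdata do not match the model's training features")
  }
  xs <- standardize(object$standardizer, x)
  setNames(drop(mlp_forward(object$net, xs)), rownames(x))
}
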