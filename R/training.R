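#' Training configuration
#'
#' Mini-batched cross-entropy training with Adam updates, an exponential
#' per-epoch learning-rate decay and early stopping on validation loss.
#' Defaults: batch size 64, initial learning rate 1e-3 multiplied by
#' `gamma = 0.9` after every training/validation cycle, patience 10 epochs,
#' Adam moment-decay constants (0.9, 0.999) with `epsilon = 1e-8`, and a
#' safety cap of 200 epochs.
#'
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param gamma Per-epoch learning-rate multiplier, in (0, 1].
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping and restoring the best checkpoint.
#' @param max_epochs Hard cap on training epochs.
#' @param beta1,beta2,epsilon Adam constants.
#' @param shuffle Reshuffle training batches each epoch (validation order is
#'   never shuffled).
#' @param seed Integer seed controlling initialization, dropout and
#'   shuffling; identical seeds give identical training histories.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, initial_lr = 1e-3, gamma = 0.9,
                         patience = 10L, max_epochs = 200L, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, shuffle = TRUE,
                         seed = 1L) {
  stopifnot(gamma > 0, gamma <= 1, patience >= 1, batch_size >= 1,
            initial_lr > 0, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 gamma = gamma, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, shuffle = isTRUE(shuffle),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Mean categorical cross-entropy
#'
#' `mean_i of -log softmax(logits_i)[label_i]`, computed with the log-sum-exp
#' stabilization.
#'
#' @param logits `n x n_classes` matrix.
#' @param labels Integer labels, 0-based, in `0 .. n_classes - 1`.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(logits, labels) {
  n <- nrow(logits)
  stopifnot(length(labels) == n)
  if (any(labels < 0 | labels >= ncol(logits)))
    stop("labels must lie in 0..", ncol(logits) - 1L)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  mean(lse - picked)
}

# gradient of mean cross-entropy wrt logits, classes x n orientation
cross_entropy_grad <- function(logits_cn, labels) {
  n <- ncol(logits_cn)
  mx <- apply(logits_cn, 2L, max)
  e <- exp(sweep(logits_cn, 2L, mx))
  p <- sweep(e, 2L, colSums(e), `/`)
  p[cbind(labels + 1L, seq_len(n))] <- p[cbind(labels + 1L, seq_len(n))] - 1
  p / n
}

#' Exponential learning-rate decay step
#'
#' @param lr Current learning rate (> 0).
#' @param gamma Decay factor.
#' @return `lr * gamma`.
#' @export
decay_lr <- function(lr, gamma) {
  stopifnot(lr > 0)
  lr * gamma
}

#' One early-stopping bookkeeping step
#'
#' A strictly smaller validation loss snapshots the model and resets the
#' counter; anything else (including an exact tie) increments it. When the
#' counter reaches the patience the caller should stop and restore
#' `state$best_model`.
#'
#' @param state List with `best_val_loss`, `epochs_since_improvement`,
#'   `best_model`, `patience`; pass the result of the previous call, or
#'   `list(best_val_loss = Inf, epochs_since_improvement = 0L, best_model =
#'   NULL, patience = p)` initially.
#' @param val_loss Validation loss of the epoch just finished (finite).
#' @param model Model after that epoch.
#' @return List `(state, stop)`.
#' @export
early_stopping_step <- function(state, val_loss, model) {
  if (!is.finite(val_loss))
    stop("non-finite validation loss: training diverged")
  if (val_loss < state$best_val_loss) {
    state$best_val_loss <- val_loss
    state$best_model <- model
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  }
  list(state = state, stop = state$epochs_since_improvement >= state$patience)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (ly$type %in% c("conv", "linear"))
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else NULL
  })
}

adam_step <- function(model, grads, opt, lr, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    o <- opt[[i]]
    o$mW <- b1 * o$mW + (1 - b1) * g$dW
    o$vW <- b2 * o$vW + (1 - b2) * g$dW^2
    o$mb <- b1 * o$mb + (1 - b1) * g$db
    o$vb <- b2 * o$vb + (1 - b2) * g$db^2
    model$layers[[i]]$W <- model$layers[[i]]$W - lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b - lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
    opt[[i]] <- o
  }
  list(model = model, opt = opt)
}

# batched evaluation without dropout; returns list(loss, acc, logits)
evaluate_split <- function(model, x, labels, rows, batch_size = 256L) {
  logits <- matrix(NA_real_, length(rows), model_n_classes(model))
  for (b in split(seq_along(rows), ceiling(seq_along(rows) / batch_size))) {
    logits[b, ] <- forward(model, x[rows[b], , , drop = FALSE], training = FALSE)
  }
  loss <- cross_entropy_loss(logits, labels[rows])
  preds <- predict_classes(logits)
  list(loss = loss, acc = mean(preds == labels[rows]), logits = logits)
}

model_n_classes <- function(model) {
  last <- model$layers[[length(model$layers)]]
  nrow(last$W)
}

#' Fit the classifier
#'
#' Runs training/validation cycles: each epoch iterates the mini-batches of
#' the training rows with dropout active and one Adam update per batch
#' (`ceiling(n_train / batch_size)` updates), then evaluates loss and
#' accuracy on all validation rows with frozen weights and dropout inactive,
#' applies the learning-rate decay, and feeds the validation loss to the
#' early-stopping rule. On stop (or at `max_epochs`) the weights from the
#' best-validation-loss epoch are restored.
#'
#' @param tensor A `trace_tensor` from [assemble()] / [preprocess_dataset()].
#' @param split A `split_index` from [split_every_third()] (or any list with
#'   `train` / `val` frames of `participant_id`, `trial_index`).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @return A list of class `gaze_cnn_fit`: `model` (restored best),
#'   `history` (data frame `epoch,train_loss,val_loss,val_acc,lr`),
#'   `best_epoch`, `stopped_early`, `n_updates`.
#' @export
fit_cnn <- function(tensor, split, net_cfg = network_config(),
                    train_cfg = train_config()) {
  rows <- split_rows(split, tensor)
  x <- tensor$values
  labels <- tensor$labels
  if (length(rows$train) < 1L || length(rows$val) < 1L)
    stop("split must provide at least one training and one validation trial")
  rng <- local_rng(train_cfg$seed)
  on.exit(restore_rng(rng))
  model <- init_network(net_cfg)
  opt <- adam_init(model)
  lr <- train_cfg$initial_lr
  es <- list(best_val_loss = Inf, epochs_since_improvement = 0L,
             best_model = NULL, patience = train_cfg$patience)
  hist <- vector("list", train_cfg$max_epochs)
  t_adam <- 0L
  n_updates <- 0L
  stopped_early <- FALSE
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_rows <- if (train_cfg$shuffle) sample(rows$train) else rows$train
    batches <- make_minibatches(length(order_rows), train_cfg$batch_size)
    ep_loss <- 0
    for (b in batches) {
      br <- order_rows[b]
      fw <- engine_forward(model, x[br, , , drop = FALSE],
                           training = TRUE, keep_cache = TRUE)
      loss <- cross_entropy_loss(t(fw$out), labels[br])
      if (!is.finite(loss))
        stop("training loss diverged (non-finite) at epoch ", epoch)
      ep_loss <- ep_loss + loss * length(br)
      dlogits <- cross_entropy_grad(fw$out, labels[br])
      bw <- engine_backward(model, fw$cache, dlogits)
      t_adam <- t_adam + 1L
      st <- adam_step(model, bw$grads, opt, lr, t_adam, train_cfg)
      model <- st$model
      opt <- st$opt
      n_updates <- n_updates + 1L
    }
    val <- evaluate_split(model, x, labels, rows$val)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / length(order_rows),
                                val_loss = val$loss, val_acc = val$acc, lr = lr)
    esr <- early_stopping_step(es, val$loss, model)
    es <- esr$state
    lr <- decay_lr(lr, train_cfg$gamma)
    if (esr$stop) { stopped_early <- TRUE; break }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  best_epoch <- history$epoch[which.min(history$val_loss)]
  structure(list(model = es$best_model, history = history,
                 best_epoch = best_epoch, stopped_early = stopped_early,
                 n_updates = n_updates, config = net_cfg,
                 train_config = train_cfg),
            class = "gaze_cnn_fit")
}

#' @export
print.gaze_cnn_fit <- function(x, ...) {
  cat("<gaze_cnn_fit> ", nrow(x$history), " epochs (best: ", x$best_epoch,
      "), final val acc ", sprintf("%.3f", x$history$val_acc[nrow(x$history)]),
      if (x$stopped_early) ", stopped early" else "", "\n", sep = "")
  invisible(x)
}
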