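#' Training configuration
#'
#' Defaults follow the published protocol: batch size 64, up to 55 epochs
#' with early stopping on dev-set accuracy, Adam with decoupled weight
#' decay 0.01, learning rate 5e-5 for the transformer arm and 5e-6 for the
#' linear-attention arm.
#'
#' @param learning_rate Adam step size. The `NULL` default resolves per arm
#'   at training time (5e-5 transformer / 5e-6 linear attention).
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of passes over the training pairs.
#' @param weight_decay decoupled (AdamW-style) weight-decay coefficient.
#' @param patience early-stopping patience in epochs (dev accuracy,
#'   min-delta 0); the best-dev-accuracy weights are restored.
#' @param seed integer RNG seed (shuffling, dropout).
#' @return list of class `lc_train_config`.
#' @export
train_config <- function(learning_rate = NULL, batch_size = 64L,
                         max_epochs = 55L, weight_decay = 0.01,
                         patience = 10L, seed = 1L) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              weight_decay = as.numeric(weight_decay),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$batch_size < 1L || cfg$max_epochs < 1L) {
    stop_data("batch_size and max_epochs must be positive")
  }
  class(cfg) <- "lc_train_config"
  cfg
}

default_lr <- function(imputation) {
  if (imputation == "transformer") 5e-5 else 5e-6
}

# one AdamW update over the nested parameter list; state holds m, v, t
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * p)
      list(p = p, m = m, v = v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Accuracy of a model on engineered samples
#'
#' @param model an [init_model()] object (evaluation mode: no dropout).
#' @param samples list of `lc_sample` objects.
#' @return list with `probs` (matrix), `pred` (integer indices, argmax with
#'   ties broken toward the lower class index), `labels`, `accuracy`.
#' @export
evaluate_model <- function(model, samples) {
  n <- length(samples)
  probs <- matrix(NA_real_, n, model$config$n_classes)
  labels <- integer(n)
  for (i in seq_len(n)) {
    fw <- model_forward(model, samples[[i]], train = FALSE)
    probs[i, ] <- fw$probs
    labels[i] <- samples[[i]]$label_index
  }
  pred <- apply(probs, 1L, which.max)   # which.max: first max = lower index
  list(probs = probs, pred = as.integer(pred), labels = labels,
       accuracy = mean(pred == labels))
}

#' Train the fusion model
#'
#' Minibatch AdamW training of the late-fusion classifier on engineered
#' training pairs, with early stopping on dev-set accuracy (patience in
#' epochs, min-delta 0) and restoration of the best-dev weights.
#' Deterministic for a fixed seed under single-threaded execution.
#'
#' @param model an [init_model()] object.
#' @param train_samples,dev_samples lists of `lc_sample` objects; train and
#'   dev must come from disjoint patient sets.
#' @param config an [train_config()].
#' @return list with `model` (trained), `history` (per-epoch data.frame:
#'   `epoch`, `loss`, `dev_accuracy`), `best_epoch`.
#' @export
train_model <- function(model, train_samples, dev_samples, config = train_config()) {
  stopifnot(inherits(model, "lc_model"), inherits(config, "lc_train_config"))
  if (!length(train_samples) || !length(dev_samples)) {
    stop_data("empty training or dev split")
  }
  lr <- config$learning_rate %||% default_lr(model$config$imputation)
  n <- length(train_samples)
  state <- list(m = zero_like(model$params), v = zero_like(model$params), t = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dev_accuracy = numeric(0))
  best_acc <- -Inf; best_params <- model$params; best_epoch <- 0L; wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        g <- zero_like(model$params)
        bl <- 0
        for (i in idx) {
          s <- train_samples[[i]]
          fw <- model_forward(model, s, train = TRUE, keep_cache = TRUE)
          g <- add_params(g, model_backward(model, fw, s$label_index))
          bl <- bl + cross_entropy_loss(fw$logits, s$label_index)
        }
        g <- scale_params(g, 1 / length(idx))
        if (lr > 0) {
          upd <- adamw_step(model$params, g, state, lr, config$weight_decay)
          model$params <- upd$params
          state <- upd$state
        }
        ep_loss <- ep_loss + bl
      }
      dev_acc <- evaluate_model(model, dev_samples)$accuracy
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / n,
                                           dev_accuracy = dev_acc))
      if (dev_acc > best_acc) {
        best_acc <- dev_acc; best_params <- model$params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch)
}
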