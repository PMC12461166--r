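#' Model configuration
#'
#' Topology of the late-fusion classifier. The published defaults are a
#' hidden size of 512 with the masked-transformer imputation encoder
#' (learning rate 5e-5) and 2048 with the linear-attention encoder
#' (learning rate 5e-6); desk-scale experiments use much smaller hidden
#' sizes.
#'
#' @param imputation which missing-data encoder feeds the baseline branch:
#'   `"transformer"` (masked scaled-dot-product attention) or
#'   `"linear_attention"` (sentinel + learned reweighting).
#' @param hidden_size model-wide hidden dimension `H`; must be divisible by
#'   `heads`. Default 512 for the transformer arm, 2048 for the linear arm.
#' @param heads,transformer_layers multi-head attention topology
#'   (transformer arm only).
#' @param lstm_layers depth of the temporal LSTM.
#' @param dropout dropout probability in the classification head
#'   (training mode only).
#' @param n_classes number of diagnostic classes.
#' @param sentinel value substituted for missing cells before embedding;
#'   -1 makes missingness linearly separable because all observed raw
#'   codings are positive.
#' @return a validated list of class `lc_model_config`.
#' @export
model_config <- function(imputation = c("transformer", "linear_attention"),
                         hidden_size = NULL, heads = 4L,
                         transformer_layers = 3L, lstm_layers = 3L,
                         dropout = 0.5, n_classes = 3L, sentinel = -1) {
  imputation <- match.arg(imputation)
  if (is.null(hidden_size)) {
    hidden_size <- if (imputation == "transformer") 512L else 2048L
  }
  cfg <- list(imputation = imputation, hidden_size = as.integer(hidden_size),
              heads = as.integer(heads),
              transformer_layers = as.integer(transformer_layers),
              lstm_layers = as.integer(lstm_layers),
              dropout = as.numeric(dropout), n_classes = as.integer(n_classes),
              sentinel = as.numeric(sentinel))
  if (cfg$hidden_size %% cfg$heads != 0L) {
    stop_data("hidden_size must be divisible by heads")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop_data("dropout must be in [0, 1)")
  class(cfg) <- "lc_model_config"
  cfg
}

unif_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' Seeded uniform initialization scaled by fan-in; LSTM forget-gate biases
#' start at 1. The gate projection and post-temporal projection carry no
#' bias so that an all-zero LSTM hidden state yields a gate of exactly 0.
#'
#' @param config an [model_config()].
#' @param n_features number of input features `K`.
#' @param seed integer RNG seed.
#' @return an object of class `lc_model`: list with `config`, `n_features`
#'   and `params`.
#' @export
init_model <- function(config, n_features, seed = 1L) {
  stopifnot(inherits(config, "lc_model_config"))
  H <- config$hidden_size
  K <- as.integer(n_features)
  with_seed(seed, {
    p <- list(
      emb_w = stats::runif(H, -1, 1),
      emb_b = stats::runif(H, -0.1, 0.1)
    )
    if (config$imputation == "transformer") {
      p$attn <- lapply(seq_len(config$transformer_layers), function(l) {
        list(Wq = unif_mat(H, H, H), Wk = unif_mat(H, H, H),
             Wv = unif_mat(H, H, H), Wo = unif_mat(H, H, H))
      })
    } else {
      p$S <- unif_mat(H, H, H)
      p$Tm <- unif_mat(H, H, H)
      p$Wbase <- unif_mat(H, K, K)
      p$bbase <- rep(0, H)
    }
    p$lstm <- lapply(seq_len(config$lstm_layers), function(l) {
      D <- if (l == 1L) 2L * K else H
      b <- rep(0, 4L * H)
      b[(H + 1L):(2L * H)] <- 1      # forget-gate bias
      list(Wx = unif_mat(4L * H, D, D), Wh = unif_mat(4L * H, H, H), b = b)
    })
    p$post_W <- unif_mat(H, H, H)    # post-temporal projection, no bias
    p$gate_w <- stats::runif(H, -1 / sqrt(H), 1 / sqrt(H))
    p$W1 <- unif_mat(H, H, H); p$b1 <- rep(0, H)
    p$W2 <- unif_mat(config$n_classes, H, H); p$b2 <- rep(0, config$n_classes)
    structure(list(config = config, n_features = K, params = p),
              class = "lc_model")
  })
}

#' Number of trainable parameters in each baseline encoder
#'
#' Direct counts of the arm-specific parameters (shared scalar embedding
#' included in both). The linear-attention encoder replaces
#' `transformer_layers * 4 * H^2` attention weights with `2 * H^2` plus a
#' `K -> H` projection, a large reduction at equal hidden size.
#'
#' @param config an [model_config()] (its `imputation` field is ignored;
#'   both arms are counted).
#' @param n_features number of input features `K`.
#' @return named numeric vector with elements `transformer` and
#'   `linear_attention`.
#' @export
count_encoder_params <- function(config, n_features) {
  n_of <- function(pp) sum(rapply(list(pp), length, how = "unlist"))
  cfg_t <- config; cfg_t$imputation <- "transformer"
  cfg_l <- config; cfg_l$imputation <- "linear_attention"
  mt <- init_model(cfg_t, n_features, seed = 1L)$params
  ml <- init_model(cfg_l, n_features, seed = 1L)$params
  c(transformer = n_of(list(mt$emb_w, mt$emb_b, mt$attn)),
    linear_attention = n_of(list(ml$emb_w, ml$emb_b, ml$S, ml$Tm,
                                 ml$Wbase, ml$bbase)))
}

#' Embed per-feature scalars into the hidden space
#'
#' Missing cells (mask 0) are replaced by the sentinel, then every scalar is
#' mapped through the shared `1 -> H` affine projection, giving one latent
#' row per feature.
#'
#' @param values numeric length-`K` vector (`NA` allowed where mask is 0).
#' @param mask binary length-`K` vector, 1 = observed.
#' @param params model parameter list (uses `emb_w`, `emb_b`).
#' @param sentinel value substituted for missing cells.
#' @return list with `E` (`K x H` matrix) and `x_s` (sentinel-substituted
#'   scalars).
#' @export
embed_features <- function(values, mask, params, sentinel = -1) {
  x_s <- ifelse(mask == 1, values, sentinel)
  if (any(!is.finite(x_s))) stop_data("non-finite observed feature value")
  K <- length(x_s); H <- length(params$emb_w)
  E <- outer(x_s, params$emb_w) + matrix(params$emb_b, K, H, byrow = TRUE)
  list(E = E, x_s = x_s)
}

row_softmax_masked <- function(S, obs) {
  # softmax over observed columns only; masked columns get weight 0
  S[, !obs] <- -Inf
  mx <- apply(S, 1L, max)
  Z <- exp(S - mx)
  Z / rowSums(Z)
}

#' Masked multi-head attention encoder
#'
#' Scaled-dot-product self-attention across the feature axis: per layer and
#' head, attention logits `Q K' / sqrt(d_k)` are computed and positions of
#' missing features are excluded from the softmax (given `-Inf` logits), so
#' each feature's new representation is a weighted average over the
#' *available* features only. After the final layer the `K x H` matrix is
#' pooled by a mean over feature positions. If every feature is missing the
#' encoder returns a zero vector with attribute `flagged = TRUE`.
#'
#' @param E `K x H` embedding matrix from [embed_features()].
#' @param mask binary length-`K` observation vector.
#' @param params model parameter list (uses `attn`).
#' @param config an [model_config()].
#' @param keep_cache keep intermediate activations (for backpropagation and
#'   inspection) in attribute `cache`.
#' @return length-`H` numeric encoding.
#' @export
masked_attention_encode <- function(E, mask, params, config, keep_cache = FALSE) {
  H <- config$hidden_size; nh <- config$heads; dk <- H %/% nh
  obs <- mask == 1
  if (!any(obs)) {
    out <- rep(0, H)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  X <- E
  layers <- vector("list", length(params$attn))
  for (l in seq_along(params$attn)) {
    w <- params$attn[[l]]
    Q <- X %*% w$Wq; Km <- X %*% w$Wk; V <- X %*% w$Wv
    O <- matrix(0, nrow(X), H)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      A <- row_softmax_masked(Q[, idx, drop = FALSE] %*%
                                t(Km[, idx, drop = FALSE]) / sqrt(dk), obs)
      A_heads[[h]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    Xout <- O %*% w$Wo
    layers[[l]] <- list(X = X, Q = Q, Km = Km, V = V, A = A_heads, O = O)
    X <- Xout
  }
  out <- colMeans(X)
  if (keep_cache) attr(out, "cache") <- list(layers = layers, obs = obs)
  out
}

# normalize positive scores to weights and reweight values: x'_k = x_k * w_k
lc_reweight <- function(values, scores) {
  if (sum(scores) == 0) stop_data("attention scores sum to zero")
  w <- scores / sum(scores)
  list(reweighted = values * w, weights = w)
}

#' Linear-attention reweighting of a feature vector
#'
#' The lightweight alternative to the transformer encoder: missing values
#' are set to the sentinel (-1); each scalar is embedded, passed through
#' `f(x) = S . relu(T . x)` with learnable `S, T` in `R^{H x H}`; the
#' `H`-dimensional output is reduced to a scalar score by a mean and made
#' strictly positive by a softplus; scores are normalized to weights
#' summing to 1; and the output is the element-wise product `x_k * w_k`.
#' Because missing cells are the only negative inputs, the map can learn to
#' down- or up-weight missingness explicitly.
#'
#' @inheritParams embed_features
#' @param params model parameter list (uses `emb_w`, `emb_b`, `S`, `Tm`).
#' @param keep_cache keep intermediates in attribute `cache`.
#' @return length-`K` reweighted vector with attribute `weights`.
#' @export
linear_attention_reweight <- function(values, mask, params, sentinel = -1,
                                      keep_cache = FALSE) {
  emb <- embed_features(values, mask, params, sentinel)
  U <- emb$E %*% t(params$Tm)
  A <- relu(U)
  Fm <- A %*% t(params$S)
  r <- rowMeans(Fm)
  s <- softplus(r)
  rw <- lc_reweight(emb$x_s, s)
  out <- rw$reweighted
  attr(out, "weights") <- rw$weights
  if (keep_cache) {
    attr(out, "cache") <- list(E = emb$E, x_s = emb$x_s, U = U, A = A,
                               r = r, s = s, w = rw$weights)
  }
  out
}

#' Project the reweighted feature vector to the hidden size
#'
#' The linear arm's baseline encoding: a single `K -> H` affine map applied
#' to the reweighted feature vector.
#'
#' @param reweighted length-`K` vector from [linear_attention_reweight()].
#' @param params model parameter list (uses `Wbase`, `bbase`).
#' @return length-`H` numeric encoding.
#' @export
encode_baseline_linear <- function(reweighted, params) {
  if (length(reweighted) != ncol(params$Wbase)) {
    stop_data("reweighted vector length %d does not match projection input %d",
              length(reweighted), ncol(params$Wbase))
  }
  as.vector(params$Wbase %*% reweighted + params$bbase)
}

lstm_cell <- function(x, h_prev, c_prev, w, H) {
  z <- as.vector(w$Wx %*% x + w$Wh %*% h_prev + w$b)
  i <- logistic(z[1:H]); f <- logistic(z[(H + 1):(2 * H)])
  g <- tanh(z[(2 * H + 1):(3 * H)]); o <- logistic(z[(3 * H + 1):(4 * H)])
  c <- f * c_prev + i * g
  h <- o * tanh(c)
  list(x = x, i = i, f = f, g = g, o = o, c = c, h = h,
       c_prev = c_prev, h_prev = h_prev)
}

#' Encode the change sequence with a multi-layer LSTM
#'
#' The change matrix's first column (ratios of the first visit to itself,
#' identically 1 where observed) carries no deviation information, so the
#' temporal sequence consists of the columns for visits `2..T`: each
#' timestep's input is the masked change vector (missing cells as 0)
#' concatenated with its observation mask. Cell and hidden states start at
#' zero and the final top-layer hidden state is returned, followed by a
#' bias-free `H x H` projection. A single-visit prefix therefore yields an
#' exactly zero temporal encoding.
#'
#' @param change `K x T` change matrix (`NA` where masked).
#' @param change_mask binary `K x T` matrix.
#' @param params model parameter list (uses `lstm`, `post_W`).
#' @param config an [model_config()].
#' @param keep_cache keep per-step activations in attribute `cache`.
#' @return length-`H` temporal encoding (attribute `h_raw` holds the
#'   unprojected final hidden state).
#' @export
encode_temporal <- function(change, change_mask, params, config,
                            keep_cache = FALSE) {
  H <- config$hidden_size
  Tn <- ncol(change)
  steps <- if (Tn >= 2L) 2:Tn else integer(0)
  if (!length(steps)) {
    out <- rep(0, H)
    attr(out, "h_raw") <- rep(0, H)
    if (keep_cache) attr(out, "cache") <- list(steps = 0L)
    return(out)
  }
  inputs <- lapply(steps, function(t) {
    v <- ifelse(change_mask[, t] == 1, change[, t], 0)
    c(v, change_mask[, t])
  })
  L <- length(params$lstm)
  cache <- vector("list", L)
  x_seq <- inputs
  for (l in seq_len(L)) {
    w <- params$lstm[[l]]
    h <- rep(0, H); cc <- rep(0, H)
    st <- vector("list", length(x_seq))
    for (t in seq_along(x_seq)) {
      st[[t]] <- lstm_cell(x_seq[[t]], h, cc, w, H)
      h <- st[[t]]$h; cc <- st[[t]]$c
    }
    cache[[l]] <- st
    x_seq <- lapply(st, `[[`, "h")
  }
  h_raw <- cache[[L]][[length(steps)]]$h
  out <- as.vector(params$post_W %*% h_raw)
  attr(out, "h_raw") <- h_raw
  if (keep_cache) attr(out, "cache") <- list(layers = cache, steps = length(steps))
  out
}

#' Scalar gate from the temporal encoding
#'
#' A bias-free linear projection `delta = w . temporal`. No squashing is
#' applied: with no change features the temporal encoding is exactly zero,
#' so the gate is exactly 0 and the fused encoding reduces to the baseline
#' path (a sigmoid would map zero to 0.5 and lose this bypass).
#'
#' @param temporal length-`H` temporal encoding.
#' @param gate_w length-`H` weight vector.
#' @return scalar gate value.
#' @export
gate_delta <- function(temporal, gate_w) {
  sum(gate_w * as.numeric(temporal))
}

#' Fuse encodings and classify
#'
#' Computes `fused = delta * temporal + (1 - delta) * baseline`, applies the
#' feed-forward head (dropout in training mode only, affine, ReLU, affine)
#' and a softmax over the diagnostic classes.
#'
#' @param baseline,temporal length-`H` encodings.
#' @param delta scalar gate.
#' @param params model parameter list (uses `W1`, `b1`, `W2`, `b2`).
#' @param config an [model_config()].
#' @param train logical; draw a dropout mask (from the current RNG stream)
#'   when `TRUE`.
#' @param keep_cache keep intermediates in attribute `cache`.
#' @return length-`n_classes` probability vector (attributes `logits`,
#'   optionally `cache`).
#' @export
fuse_and_classify <- function(baseline, temporal, delta, params, config,
                              train = FALSE, keep_cache = FALSE) {
  baseline <- as.numeric(baseline); temporal <- as.numeric(temporal)
  if (length(baseline) != length(temporal)) {
    stop_data("baseline and temporal encodings differ in dimension (%d vs %d)",
              length(baseline), length(temporal))
  }
  fused <- delta * temporal + (1 - delta) * baseline
  if (train && config$dropout > 0) {
    keep <- (stats::runif(length(fused)) >= config$dropout) / (1 - config$dropout)
  } else {
    keep <- NULL
  }
  fd <- if (is.null(keep)) fused else fused * keep
  z1 <- as.vector(params$W1 %*% fd + params$b1)
  a1 <- relu(z1)
  logits <- as.vector(params$W2 %*% a1 + params$b2)
  probs <- softmax_vec(logits)
  attr(probs, "logits") <- logits
  if (keep_cache) {
    attr(probs, "cache") <- list(fused = fused, keep = keep, fd = fd,
                                 z1 = z1, a1 = a1, logits = logits,
                                 baseline = baseline, temporal = temporal,
                                 delta = delta)
  }
  probs
}

#' Mean cross-entropy loss
#'
#' Computed from logits via a log-sum-exp for numerical stability; the
#' batch loss is the mean of per-sample losses.
#'
#' @param logits numeric vector (one sample) or matrix with one row per
#'   sample.
#' @param labels integer class indices in `1..n_classes`.
#' @return scalar mean cross-entropy.
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(logits))) stop_data("label out of range")
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}

#' Full forward pass for one engineered sample
#'
#' Runs the configured baseline encoder, the temporal LSTM encoder, the
#' gate and the classification head.
#'
#' @param model an [init_model()] object.
#' @param sample an `lc_sample` from [engineer_sample()].
#' @param train logical; enables dropout (consumes RNG draws).
#' @param keep_cache keep all intermediates for backpropagation.
#' @return list with `probs`, `logits`, `delta`, `baseline_h`, `temporal_h`
#'   and (if requested) `cache`.
#' @export
model_forward <- function(model, sample, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  emb <- embed_features(sample$baseline, sample$baseline_mask, p, cfg$sentinel)
  all_missing <- !any(sample$baseline_mask == 1)
  if (cfg$imputation == "transformer") {
    base_h <- masked_attention_encode(emb$E, sample$baseline_mask, p, cfg,
                                      keep_cache = keep_cache)
    base_cache <- attr(base_h, "cache")
    xprime <- NULL
  } else {
    if (all_missing) {
      base_h <- rep(0, cfg$hidden_size)
      attr(base_h, "flagged") <- TRUE
      base_cache <- NULL
      xprime <- NULL
    } else {
      xprime <- linear_attention_reweight(sample$baseline,
                                          sample$baseline_mask, p,
                                          cfg$sentinel, keep_cache = keep_cache)
      base_h <- encode_baseline_linear(as.numeric(xprime), p)
      base_cache <- attr(xprime, "cache")
    }
  }
  temporal <- encode_temporal(sample$change, sample$change_mask, p, cfg,
                              keep_cache = keep_cache)
  delta <- gate_delta(temporal, p$gate_w)
  probs <- fuse_and_classify(as.numeric(base_h), as.numeric(temporal), delta,
                             p, cfg, train = train, keep_cache = keep_cache)
  out <- list(probs = as.numeric(probs), logits = attr(probs, "logits"),
              delta = delta, baseline_h = as.numeric(base_h),
              temporal_h = as.numeric(temporal))
  if (keep_cache) {
    out$cache <- list(
      emb = emb, base = base_cache, base_flagged = all_missing,
      xprime = if (!is.null(xprime)) as.numeric(xprime) else NULL,
      temporal = attr(temporal, "cache"),
      h_raw = attr(temporal, "h_raw"),
      head = attr(probs, "cache"),
      mask = sample$baseline_mask
    )
  }
  out
}
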