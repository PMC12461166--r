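# Hand-written reverse-mode gradients for the fusion model. Verified against
# central finite differences in the test suite; every formula below mirrors a
# forward step in model.R.

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

add_params <- function(a, b) {
  if (is.list(a)) Map(add_params, a, b) else a + b
}

scale_params <- function(a, s) {
  if (is.list(a)) lapply(a, scale_params, s = s) else a * s
}

# gradient of mean cross-entropy wrt logits for one sample (no 1/batch here)
dlogits_ce <- function(logits, label) {
  p <- softmax_vec(logits)
  p[label] <- p[label] - 1
  p
}

# backward through the classification head + gate + fusion
# returns list(grads-partial, dbase, dtemporal_vec)
backward_head <- function(p, hc, dlogits, g) {
  g$W2 <- g$W2 + outer(dlogits, hc$a1)
  g$b2 <- g$b2 + dlogits
  da1 <- as.vector(t(p$W2) %*% dlogits)
  dz1 <- da1 * (hc$z1 > 0)
  g$W1 <- g$W1 + outer(dz1, hc$fd)
  g$b1 <- g$b1 + dz1
  dfd <- as.vector(t(p$W1) %*% dz1)
  dfused <- if (is.null(hc$keep)) dfd else dfd * hc$keep
  ddelta <- sum(dfused * (hc$temporal - hc$baseline))
  dtemporal <- dfused * hc$delta + p$gate_w * ddelta
  dbase <- dfused * (1 - hc$delta)
  g$gate_w <- g$gate_w + ddelta * hc$temporal
  list(g = g, dbase = dbase, dtemporal = dtemporal)
}

# backward through the LSTM stack; dh_top is the gradient wrt the final
# top-layer hidden state. Returns updated grads.
backward_lstm <- function(p, cache, dh_top, g, H) {
  L <- length(p$lstm)
  Tn <- length(cache$layers[[1L]])
  # external dh per layer/timestep (from the layer above, or dh_top)
  dh_ext <- lapply(seq_len(L), function(l) {
    lapply(seq_len(Tn), function(t) rep(0, H))
  })
  dh_ext[[L]][[Tn]] <- dh_top
  for (l in L:1) {
    w <- p$lstm[[l]]
    st <- cache$layers[[l]]
    dh_rec <- rep(0, H); dc_rec <- rep(0, H)
    for (t in Tn:1) {
      s <- st[[t]]
      dh <- dh_ext[[l]][[t]] + dh_rec
      tc <- tanh(s$c)
      do <- dh * tc
      dc <- dc_rec + dh * s$o * (1 - tc^2)
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$c_prev
      dc_rec <- dc * s$f
      dz <- c(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
              dg * (1 - s$g^2), do * s$o * (1 - s$o))
      g$lstm[[l]]$Wx <- g$lstm[[l]]$Wx + outer(dz, s$x)
      g$lstm[[l]]$Wh <- g$lstm[[l]]$Wh + outer(dz, s$h_prev)
      g$lstm[[l]]$b <- g$lstm[[l]]$b + dz
      dh_rec <- as.vector(t(w$Wh) %*% dz)
      if (l > 1L) {
        dh_ext[[l - 1L]][[t]] <- dh_ext[[l - 1L]][[t]] +
          as.vector(t(w$Wx) %*% dz)
      }
    }
  }
  g
}

# backward through the masked multi-head attention encoder.
# dbase: gradient wrt the pooled H-vector. Returns list(g, dE).
backward_attention <- function(p, cfg, cache, dbase, g) {
  H <- cfg$hidden_size; nh <- cfg$heads; dk <- H %/% nh
  layers <- cache$layers
  K <- nrow(layers[[1L]]$X)
  # pooling: colMeans -> every feature row receives dbase / K
  dX <- matrix(dbase, K, H, byrow = TRUE) / K
  for (l in rev(seq_along(layers))) {
    lc <- layers[[l]]; w <- p$attn[[l]]
    g$attn[[l]]$Wo <- g$attn[[l]]$Wo + t(lc$O) %*% dX
    dO <- dX %*% t(w$Wo)
    dQ <- matrix(0, K, H); dK <- matrix(0, K, H); dV <- matrix(0, K, H)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      A <- lc$A[[h]]
      dO_h <- dO[, idx, drop = FALSE]
      dA <- dO_h %*% t(lc$V[, idx, drop = FALSE])
      dV[, idx] <- t(A) %*% dO_h
      dS <- A * (dA - rowSums(dA * A))   # row-wise softmax backward
      dQ[, idx] <- dS %*% lc$Km[, idx, drop = FALSE] / sqrt(dk)
      dK[, idx] <- t(dS) %*% lc$Q[, idx, drop = FALSE] / sqrt(dk)
    }
    g$attn[[l]]$Wq <- g$attn[[l]]$Wq + t(lc$X) %*% dQ
    g$attn[[l]]$Wk <- g$attn[[l]]$Wk + t(lc$X) %*% dK
    g$attn[[l]]$Wv <- g$attn[[l]]$Wv + t(lc$X) %*% dV
    dX <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  }
  list(g = g, dE = dX)
}

# backward through the linear-attention reweighting + K->H projection.
# dbase: gradient wrt the H-dim baseline encoding. Returns list(g, dE).
backward_linear_attention <- function(p, cache, dbase, g, xprime) {
  g$Wbase <- g$Wbase + outer(dbase, xprime)
  g$bbase <- g$bbase + dbase
  dxprime <- as.vector(t(p$Wbase) %*% dbase)
  x_s <- cache$x_s; w <- cache$w; s <- cache$s; r <- cache$r
  dw <- dxprime * x_s
  ds <- (dw - sum(dw * w)) / sum(s)
  dr <- ds * logistic(r)                  # softplus'
  H <- ncol(cache$E)
  dFm <- outer(dr, rep(1 / H, H))         # rowMeans backward
  g$S <- g$S + t(dFm) %*% cache$A
  dA <- dFm %*% p$S
  dU <- dA * (cache$U > 0)
  g$Tm <- g$Tm + t(dU) %*% cache$E
  dE <- dU %*% p$Tm
  list(g = g, dE = dE)
}

#' Gradients of the per-sample cross-entropy loss
#'
#' Reverse-mode gradients of `-log p(label)` for one sample with respect to
#' every model parameter, given a forward pass run with
#' `keep_cache = TRUE`.
#'
#' @param model an [init_model()] object.
#' @param fwd result of [model_forward()] with `keep_cache = TRUE`.
#' @param label integer class index in `1..n_classes`.
#' @return parameter-shaped list of gradients.
#' @export
model_backward <- function(model, fwd, label) {
  p <- model$params; cfg <- model$config
  H <- cfg$hidden_size
  cache <- fwd$cache
  g <- zero_like(p)
  dlog <- dlogits_ce(fwd$logits, label)
  hb <- backward_head(p, cache$head, dlog, g)
  g <- hb$g
  # temporal branch
  if (!is.null(cache$temporal) && cache$temporal$steps > 0L) {
    g$post_W <- g$post_W + outer(hb$dtemporal, cache$h_raw)
    dh_top <- as.vector(t(p$post_W) %*% hb$dtemporal)
    g <- backward_lstm(p, cache$temporal, dh_top, g, H)
  }
  # baseline branch
  if (!cache$base_flagged) {
    if (cfg$imputation == "transformer") {
      ba <- backward_attention(p, cfg, cache$base, hb$dbase, g)
    } else {
      ba <- backward_linear_attention(p, cache$base, hb$dbase, g, cache$xprime)
    }
    g <- ba$g
    g$emb_w <- g$emb_w + as.vector(t(ba$dE) %*% cache$emb$x_s)
    g$emb_b <- g$emb_b + colSums(ba$dE)
  }
  g
}
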