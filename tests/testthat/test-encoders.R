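test_that("embedding maps scalars through the shared projection, sentinel for missing", {
  m <- tiny_model("linear_attention", K = 4L, H = 8L)
  emb <- embed_features(c(2, NA, 1, 3), c(1, 0, 1, 1), m$params, sentinel = -1)
  expect_equal(dim(emb$E), c(4L, 8L))
  expect_equal(emb$x_s[2], -1)
  expect_equal(emb$E[2, ], -1 * m$params$emb_w + m$params$emb_b)
  # zero projection weight: embeddings reduce to the bias
  p0 <- m$params; p0$emb_w <- p0$emb_w * 0
  e0 <- embed_features(c(2, NA, 1, 3), c(1, 0, 1, 1), p0)
  expect_true(all(apply(e0$E, 1, function(r) all(r == p0$emb_b))))
  expect_error(embed_features(c(Inf, 1), c(1, 1), m$params), "non-finite")
})

test_that("masked attention ignores missing features entirely", {
  m <- tiny_model("transformer", K = 6L, H = 8L)
  cfg <- m$config
  vals <- c(1.2, 2, NA, 0.7, NA, 1.5)
  mask <- c(1, 1, 0, 1, 0, 1)
  enc <- function(v) {
    e <- embed_features(v, mask, m$params, cfg$sentinel)
    masked_attention_encode(e$E, mask, m$params, cfg)
  }
  base <- enc(vals)
  expect_length(base, 8L)
  # perturbing masked cells' stored values changes nothing, bit for bit
  for (rep in 1:5) {
    v2 <- vals
    v2[mask == 0] <- stats::runif(2, -100, 100)
    expect_identical(enc(v2), base)
  }
  # single observed feature: output depends only on that feature
  m1 <- c(1, 0, 0, 0, 0, 0)
  e1 <- embed_features(c(2, NA, NA, NA, NA, NA), m1, m$params, -1)
  o1 <- masked_attention_encode(e1$E, m1, m$params, cfg, keep_cache = TRUE)
  A <- attr(o1, "cache")$layers[[1]]$A[[1]]
  expect_true(all(A[, 1] == 1))
  expect_true(all(A[, -1] == 0))
  # all-missing: zero vector, flagged
  o0 <- masked_attention_encode(e1$E, rep(0, 6), m$params, cfg)
  expect_equal(as.numeric(o0), rep(0, 8))
  expect_true(attr(o0, "flagged"))
})

test_that("equal logits spread attention uniformly over observed features", {
  m <- tiny_model("transformer", K = 4L, H = 8L)
  p <- m$params
  p$attn[[1]]$Wq <- p$attn[[1]]$Wq * 0   # Q = 0 -> all logits equal
  mask <- rep(1, 4)
  e <- embed_features(c(1, 2, 3, 4), mask, p, -1)
  out <- masked_attention_encode(e$E, mask, p, m$config, keep_cache = TRUE)
  A <- attr(out, "cache")$layers[[1]]$A[[1]]
  expect_equal(unname(A), matrix(0.25, 4, 4))
})

test_that("linear-attention weights normalize, reweight, and permute consistently", {
  # hand oracle: scores (3, 1) on values (2, 4) -> (1.5, 1.0)
  rw <- longicog:::lc_reweight(c(2, 4), c(3, 1))
  expect_equal(rw$reweighted, c(1.5, 1.0))
  expect_equal(sum(rw$weights), 1)
  expect_error(longicog:::lc_reweight(c(1, 1), c(0, 0)), "zero")

  m <- tiny_model("linear_attention", K = 6L, H = 8L)
  set.seed(41)
  for (i in 1:50) {
    mask <- stats::rbinom(6, 1, 0.7)
    vals <- ifelse(mask == 1, stats::runif(6, 0.1, 5), NA)
    out <- linear_attention_reweight(vals, mask, m$params, -1)
    w <- attr(out, "weights")
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    # missing-invariance: perturb masked stored values
    v2 <- vals
    v2[mask == 0] <- stats::runif(sum(mask == 0), -50, 50)
    out2 <- linear_attention_reweight(v2, mask, m$params, -1)
    expect_identical(as.numeric(out2), as.numeric(out))
    # permutation consistency
    perm <- sample(6)
    outp <- linear_attention_reweight(vals[perm], mask[perm], m$params, -1)
    expect_equal(as.numeric(outp), as.numeric(out)[perm])
    expect_equal(attr(outp, "weights"), w[perm])
  }
  # K = 1 degenerate: weight 1, value passed through
  m1 <- tiny_model("linear_attention", K = 1L, H = 8L)
  o1 <- linear_attention_reweight(2.5, 1, m1$params, -1)
  expect_equal(as.numeric(o1), 2.5)
})

test_that("baseline projection is affine and validates dimensions", {
  m <- tiny_model("linear_attention", K = 5L, H = 8L)
  x <- stats::runif(5)
  out <- encode_baseline_linear(x, m$params)
  expect_equal(out, as.vector(m$params$Wbase %*% x + m$params$bbase))
  expect_equal(encode_baseline_linear(rep(0, 5), m$params), m$params$bbase)
  expect_error(encode_baseline_linear(rep(0, 4), m$params), "does not match")
})

test_that("linear-attention encoder has fewer parameters than the transformer", {
  for (H in c(8L, 32L, 128L)) {
    cfg <- model_config("transformer", hidden_size = H, heads = 4L)
    counts <- count_encoder_params(cfg, n_features = 14L)
    expect_lt(counts["linear_attention"], counts["transformer"])
  }
})
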