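# Shared fixtures, all built in code.

# A hand-built cohort with known visit dates/labels for pipeline tests.
# Spans are in years relative to 2010-01-01; 365.25-day years are used so
# integer "years" land exactly on the convention.
hand_cohort <- function(records, n_feat = 2L) {
  spec <- make_feature_spec(n_feat, 0L)
  rows <- do.call(rbind, lapply(names(records), function(id) {
    r <- records[[id]]
    v <- data.frame(
      patient_id = id,
      visit_date = as.Date("2010-01-01") + round(r$years * 365.25),
      label = r$labels,
      stringsAsFactors = FALSE
    )
    for (f in spec$name) v[[f]] <- seq_len(nrow(v)) + 0.5
    v
  }))
  cohort(rows, spec)
}

# random engineered sample for model-level tests
random_sample <- function(K, Tn, label = 2L, p_obs = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- stats::rbinom(K, 1, p_obs)
  mask[1] <- 1
  vals <- ifelse(mask == 1, stats::runif(K, 0.5, 3), NA_real_)
  C <- matrix(stats::runif(K * Tn, 0.5, 2), K, Tn)
  C[, 1] <- 1
  M <- matrix(stats::rbinom(K * Tn, 1, p_obs), K, Tn)
  C[M == 0] <- NA_real_
  structure(list(baseline = vals, baseline_mask = mask, change = C,
                 change_mask = M, target_label = LABEL_LEVELS[label],
                 label_index = as.integer(label), horizon_years = 4,
                 patient_id = "PX"),
            class = "lc_sample")
}

tiny_model <- function(arm, K = 5L, H = 8L, seed = 7L, dropout = 0) {
  cfg <- model_config(arm, hidden_size = H, heads = 2L, dropout = dropout)
  init_model(cfg, K, seed = seed)
}

# flatten / restore parameters for finite-difference checks
flat_params <- function(p) unlist(p, use.names = FALSE)

set_flat_params <- function(model, theta) {
  model$params <- utils::relist(theta, utils::as.relistable(model$params))
  model
}

# brute-force one-vs-rest counts by enumerating every (true, pred) outcome
brute_ovr <- function(cm, c_i) {
  outcomes <- do.call(rbind, lapply(1:3, function(t) {
    do.call(rbind, lapply(1:3, function(p) {
      if (cm[t, p] > 0) {
        matrix(rep(c(t, p), cm[t, p]), ncol = 2, byrow = TRUE)
      }
    }))
  }))
  tp <- sum(outcomes[, 1] == c_i & outcomes[, 2] == c_i)
  fp <- sum(outcomes[, 1] != c_i & outcomes[, 2] == c_i)
  fn <- sum(outcomes[, 1] == c_i & outcomes[, 2] != c_i)
  tn <- sum(outcomes[, 1] != c_i & outcomes[, 2] != c_i)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       ovr_accuracy = (tp + tn) / nrow(outcomes))
}

numeric_grad <- function(model, s, idx, eps = 1e-5) {
  theta <- flat_params(model$params)
  loss_at <- function(th) {
    m2 <- set_flat_params(model, th)
    cross_entropy_loss(model_forward(m2, s)$logits, s$label_index)
  }
  vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, numeric(1))
}
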