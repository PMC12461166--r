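#' Confusion matrix for the three diagnostic classes
#'
#' @param true,pred vectors of labels (`Control`/`aMCI`/`AD` or integer
#'   indices 1..3). Rows are true labels, columns predicted.
#' @return a 3x3 integer matrix with dimnames.
#' @export
confusion_matrix3 <- function(true, pred) {
  to_idx <- function(x) if (is.numeric(x)) as.integer(x) else label_severity(x)
  t_i <- factor(to_idx(true), levels = 1:3)
  p_i <- factor(to_idx(pred), levels = 1:3)
  m <- as.matrix(table(t_i, p_i))
  dimnames(m) <- list(true = LABEL_LEVELS, pred = LABEL_LEVELS)
  m
}

#' One-vs-rest metrics from a multiclass confusion matrix
#'
#' The class under test is treated as "positive" and any other predicted
#' outcome as "negative": `TP` is the diagonal entry, `FP` the rest of the
#' predicted column, `FN` the rest of the true row, `TN` everything else.
#' Precision `TP/(TP+FP)` and recall `TP/(TP+FN)` are `NA` (flagged) when
#' their denominator is zero; one-vs-rest accuracy is `(TP+TN)/total`.
#'
#' @param cm a square confusion matrix (rows true, columns predicted).
#' @param class class index (1-based) or label name.
#' @return list with `precision`, `recall`, `ovr_accuracy`, and the counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
ovr_extract <- function(cm, class) {
  c_i <- if (is.character(class)) match(class, rownames(cm)) else as.integer(class)
  stopifnot(!is.na(c_i), c_i >= 1L, c_i <= nrow(cm))
  tp <- cm[c_i, c_i]
  fp <- sum(cm[, c_i]) - tp
  fn <- sum(cm[c_i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ovr_accuracy = (tp + tn) / sum(cm),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

# rank-based (Mann-Whitney) AUC with midrank tie handling
rank_auc <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest AUC per class and macro average
#'
#' Rank-based (Mann-Whitney) AUC of each class's predicted probability
#' against the binary indicator `label == class`, with midrank tie
#' handling. Classes with no positive or no negative example are `NA` and
#' excluded from the macro average with a warning.
#'
#' @param scores numeric matrix `n x n_classes` of class probabilities.
#' @param labels integer class indices (1-based) or label names.
#' @return list with `auc` (per-class vector) and `macro`.
#' @export
ovr_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- label_severity(labels)
  stopifnot(nrow(scores) == length(labels))
  auc <- vapply(seq_len(ncol(scores)), function(c_i) {
    rank_auc(scores[, c_i], labels == c_i)
  }, numeric(1))
  names(auc) <- LABEL_LEVELS[seq_len(ncol(scores))]
  if (anyNA(auc)) {
    warning("degenerate class(es) excluded from macro AUC: ",
            paste(names(auc)[is.na(auc)], collapse = ", "))
  }
  list(auc = auc, macro = mean(auc, na.rm = TRUE))
}

#' Cross-fold t confidence band
#'
#' Two-tailed 95% Student-t band across the `k` per-fold values of a
#' metric: half-width `t_{0.975, k-1} * sd / sqrt(k)`, reported as
#' mean +/- half-width.
#'
#' @param values numeric vector of per-fold metric values (`NA` dropped).
#' @param level confidence level.
#' @return list with `mean`, `half_width`, `lower`, `upper`, `k`.
#' @export
fold_band <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2L) stop_data("need >= 2 fold values for a confidence band")
  m <- mean(values)
  hw <- stats::qt(1 - (1 - level) / 2, df = k - 1) * stats::sd(values) / sqrt(k)
  list(mean = m, half_width = hw, lower = m - hw, upper = m + hw, k = k)
}

format_band <- function(band, digits = 2L, scale = 100) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          band$mean * scale, band$half_width * scale)
}
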