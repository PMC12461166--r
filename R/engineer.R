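#' Fit control-population normalization statistics
#'
#' Computes per-feature mean and sample SD (n - 1 convention) over the
#' observed values of all visits of *training-split control patients*
#' (patients whose final status is `Control`). Validation samples are
#' always normalized with statistics fitted on the training split — never
#' refitted — to prevent data contamination. Features with fewer than two
#' observed control values or zero variance are flagged and passed through
#' as missing by [zscore_baseline()].
#'
#' @param x an `lc_cohort`.
#' @param train_patient_ids the training-split patient ids.
#' @return an object of class `lc_control_stats`: list with `mean`, `sd`
#'   (named numeric), `n_control` (number of control patients used) and
#'   `flagged` (character vector of unusable features).
#' @export
fit_control_stats <- function(x, train_patient_ids) {
  stopifnot(inherits(x, "lc_cohort"))
  fl <- final_labels(x)
  ctrl <- fl$patient_id[fl$final_label == "Control" &
                          fl$patient_id %in% train_patient_ids]
  if (length(ctrl) < 2L) {
    stop_data("need >= 2 control patients in the training split (got %d)",
              length(ctrl))
  }
  v <- x$visits[x$visits$patient_id %in% ctrl, , drop = FALSE]
  feats <- x$features$name
  mu <- sd <- stats::setNames(rep(NA_real_, length(feats)), feats)
  flagged <- character(0)
  for (f in feats) {
    obs <- v[[f]][!is.na(v[[f]])]
    if (length(obs) < 2L || stats::sd(obs) == 0) {
      flagged <- c(flagged, f)
    } else {
      mu[f] <- mean(obs)
      sd[f] <- stats::sd(obs)
    }
  }
  structure(list(mean = mu, sd = sd, n_control = length(ctrl),
                 flagged = flagged),
            class = "lc_control_stats")
}

#' Z-score a visit's feature values against the control population
#'
#' `(x - mean) / sd` per observed value; missing values stay missing with
#' mask 0, and flagged features (unusable control statistics) pass through
#' as missing.
#'
#' @param values named numeric vector (one entry per feature, `NA` =
#'   missing).
#' @param stats an [fit_control_stats()] object.
#' @return list with `baseline` (numeric vector, `NA` where masked) and
#'   `mask` (1 = observed, 0 = missing).
#' @export
zscore_baseline <- function(values, stats) {
  stopifnot(inherits(stats, "lc_control_stats"))
  feats <- names(stats$mean)
  x <- values[feats]
  z <- (x - stats$mean) / stats$sd
  z[feats %in% stats$flagged] <- NA_real_
  mask <- as.numeric(!is.na(z))
  z[mask == 0] <- NA_real_
  list(baseline = stats::setNames(as.numeric(z), feats), mask = mask)
}

#' Change features: ratios against the patient's first visit
#'
#' Entry `(j, t)` is `x_j(t) / x_j(1)` computed on *raw* (pre-z-score)
#' values, defined only when both are observed and the first-visit value is
#' non-zero; the first column equals 1 wherever the first-visit value is
#' observed. Undefined cells (missing value, missing or zero denominator)
#' are masked. These ratios surface intra-personal deviation from the
#' patient's own baseline over time.
#'
#' @param visit_values numeric matrix `features x timesteps` of raw values
#'   (`NA` = missing), e.g. `t(as.matrix(visits[prefix_rows, feature_names]))`.
#' @return list with `change` (matrix, `NA` where masked) and `mask`
#'   (binary matrix of the same shape).
#' @export
change_ratios <- function(visit_values) {
  stopifnot(is.matrix(visit_values), ncol(visit_values) >= 1L)
  first <- visit_values[, 1L]
  denom_ok <- !is.na(first) & first != 0
  ratio <- sweep(visit_values, 1L, first, `/`)
  ratio[!denom_ok, ] <- NA_real_
  mask <- (!is.na(ratio)) * 1
  ratio[mask == 0] <- NA_real_
  list(change = ratio, mask = mask)
}

#' Mask static features out of the change set
#'
#' Static variables (family history etc.) have a constant change ratio of 1,
#' which adds no information; they are masked out of the "change" set at
#' every timestep (as if unavailable) and retained only in the "baseline"
#' set.
#'
#' @param change result of [change_ratios()].
#' @param spec an [feature_spec()] with rownames matching the change matrix.
#' @return the `change` list with static rows masked.
#' @export
mask_static_in_change <- function(change, spec) {
  st <- spec$name[spec$static]
  if (length(st)) {
    rows <- rownames(change$change) %in% st
    change$change[rows, ] <- NA_real_
    change$mask[rows, ] <- 0
  }
  change
}

#' Engineer one (prefix, target) pair into model-ready arrays
#'
#' Produces the two feature sets the fusion model consumes:
#' \describe{
#'   \item{baseline}{the *last* prefix visit's values, z-scored against the
#'     training control population, with observation mask;}
#'   \item{change}{the `features x prefix-length` matrix of ratios against
#'     the first prefix visit (raw values), static features masked, with
#'     observation mask.}
#' }
#'
#' @param pair one row of an `lc_pairs` table.
#' @param x the `lc_cohort` the pair indexes into.
#' @param stats an [fit_control_stats()] object from the training split.
#' @return an `lc_sample`: list with `baseline`, `baseline_mask`, `change`,
#'   `change_mask`, `target_label`, `label_index` (1 = Control, 2 = aMCI,
#'   3 = AD), `horizon_years`, `patient_id`.
#' @export
engineer_sample <- function(pair, x, stats) {
  feats <- x$features$name
  prefix <- pair$prefix_rows[[1L]]
  raw <- t(as.matrix(x$visits[prefix, feats, drop = FALSE]))
  rownames(raw) <- feats
  last_vals <- stats::setNames(raw[, ncol(raw)], feats)
  bl <- zscore_baseline(last_vals, stats)
  ch <- mask_static_in_change(change_ratios(raw), x$features)
  structure(list(
    baseline = bl$baseline, baseline_mask = bl$mask,
    change = ch$change, change_mask = ch$mask,
    target_label = pair$target_label,
    label_index = label_severity(pair$target_label),
    horizon_years = pair$horizon_years,
    patient_id = pair$patient_id
  ), class = "lc_sample")
}

#' Engineer every pair in a table
#'
#' @param pairs an `lc_pairs` table.
#' @inheritParams engineer_sample
#' @return list of `lc_sample` objects.
#' @export
engineer_pairs <- function(pairs, x, stats) {
  lapply(seq_len(nrow(pairs)), function(i) {
    engineer_sample(pairs[i, , drop = FALSE], x, stats)
  })
}

#' Serialize / read control statistics as JSON
#'
#' @param stats an `lc_control_stats`.
#' @param path file path.
#' @return `read_control_stats()` returns the `lc_control_stats`.
#' @export
write_control_stats <- function(stats, path) {
  obj <- list(mean = as.list(stats$mean), sd = as.list(stats$sd),
              n_control = stats$n_control, flagged = stats$flagged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_control_stats
#' @export
read_control_stats <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_vec <- function(lst) {
    vapply(lst, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
           numeric(1))
  }
  structure(list(
    mean = num_vec(raw$mean), sd = num_vec(raw$sd),
    n_control = as.integer(raw$n_control),
    flagged = as.character(unlist(raw$flagged))
  ), class = "lc_control_stats")
}
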