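#' Filter patients by visit count and first-to-last span
#'
#' Retains patients with at least `min_visits` dated visits whose first and
#' last visits are between `min_span` and `max_span` years apart (fractional
#' years, 365.25-day convention). This realises the 3-to-10-year eligibility
#' window for long-horizon prediction.
#'
#' @param x an `lc_cohort`.
#' @param min_span,max_span span bounds in years (inclusive).
#' @param min_visits minimum number of visits.
#' @return the filtered `lc_cohort`.
#' @export
filter_eligibility <- function(x, min_span = 3.0, max_span = 10.0, min_visits = 2L) {
  stopifnot(inherits(x, "lc_cohort"))
  rows <- patient_rows(x)
  keep <- vapply(rows, function(idx) {
    if (length(idx) < min_visits) return(FALSE)
    d <- x$visits$visit_date[idx]
    span <- years_between(d[1], d[length(d)])
    span >= min_span && span <= max_span
  }, logical(1))
  subset_patients(x, names(rows)[keep])
}

#' Exclude patients who progress to a non-AD dementia
#'
#' Patients with any `OtherDementia` visit label (e.g. Parkinson's or
#' frontotemporal dementia) are removed wholesale; only the
#' Control/aMCI/AD spectrum is analysed. Reversions (a later visit with a
#' *less* severe label) are handled at the training-pair level by
#' [drop_reversion_pairs()], not by removing patients.
#'
#' @param x an `lc_cohort` whose labels are in
#'   `Control`, `aMCI`, `AD`, `OtherDementia`.
#' @return the filtered `lc_cohort`.
#' @export
drop_non_ad_and_reversions <- function(x) {
  stopifnot(inherits(x, "lc_cohort"))
  lab <- x$visits$label
  known <- c(LABEL_LEVELS, "OtherDementia")
  if (!all(lab %in% known)) {
    stop_data("unknown diagnosis label(s): %s",
              paste(unique(lab[!lab %in% known]), collapse = ", "))
  }
  bad <- unique(x$visits$patient_id[lab == "OtherDementia"])
  subset_patients(x, setdiff(unique(x$visits$patient_id), bad))
}

#' Balance classes by uniform down-sampling without replacement
#'
#' Finds the class with the smallest count `m` and draws exactly `m`
#' members per class uniformly without replacement, so the returned set has
#' `3 * m` members in total. Deterministic given `seed`.
#'
#' @param labels character vector of class labels (one per sampling unit,
#'   here: a patient's final status).
#' @param seed integer RNG seed.
#' @return integer vector of retained indices into `labels`, sorted.
#' @export
balance_classes <- function(labels, seed = 1L) {
  sev <- label_severity(labels)   # validates labels
  counts <- table(factor(labels, levels = LABEL_LEVELS))
  if (any(counts == 0)) {
    stop_data("cannot balance: class(es) with zero members: %s",
              paste(names(counts)[counts == 0], collapse = ", "))
  }
  m <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(LABEL_LEVELS, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) == m) idx else sample(idx, m)
    }))
    sort(keep)
  })
}

new_pairs <- function(patient_id, prefix_rows, target_row, target_label,
                      horizon_years) {
  out <- data.frame(patient_id = patient_id,
                    target_row = target_row,
                    target_label = target_label,
                    horizon_years = horizon_years,
                    stringsAsFactors = FALSE)
  out$prefix_rows <- prefix_rows
  class(out) <- c("lc_pairs", "data.frame")
  out
}

empty_pairs <- function() {
  new_pairs(character(0), list(), integer(0), character(0), numeric(0))
}

#' Prefix augmentation: one training pair per visit transition
#'
#' For a patient with `t` visits `x_1, ..., x_t` this produces the `t - 1`
#' training pairs `({x_1..x_{j-1}}, x_j)` for `j = 2..t`: every proper
#' prefix of the record predicts the diagnosis at the next visit. The
#' resulting horizons span roughly 1-10 years, training the model across
#' the whole prediction range. Patients with fewer than 2 visits yield no
#' pairs. Reversion pairs are *not* removed here; pass the result through
#' [drop_reversion_pairs()].
#'
#' @param x an `lc_cohort`.
#' @param patient_ids optional subset of patients to augment.
#' @return an `lc_pairs` data.frame with one row per pair: `patient_id`,
#'   `prefix_rows` (list of visit row indices into `x$visits`),
#'   `target_row`, `target_label`, `horizon_years` (last prefix visit to
#'   target visit).
#' @export
augment_prefixes <- function(x, patient_ids = NULL) {
  stopifnot(inherits(x, "lc_cohort"))
  rows <- patient_rows(x)
  if (!is.null(patient_ids)) rows <- rows[names(rows) %in% patient_ids]
  res <- lapply(rows, function(idx) {
    t <- length(idx)
    if (t < 2L) return(NULL)
    js <- 2:t
    list(
      prefix = lapply(js, function(j) idx[seq_len(j - 1L)]),
      target = idx[js],
      horizon = vapply(js, function(j) {
        years_between(x$visits$visit_date[idx[j - 1L]], x$visits$visit_date[idx[j]])
      }, numeric(1))
    )
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_pairs())
  n_per <- vapply(res, function(r) length(r$target), integer(1))
  tr <- unlist(lapply(res, `[[`, "target"), use.names = FALSE)
  new_pairs(
    patient_id = rep(names(res), n_per),
    prefix_rows = unlist(lapply(res, `[[`, "prefix"), recursive = FALSE),
    target_row = tr,
    target_label = x$visits$label[tr],
    horizon_years = unlist(lapply(res, `[[`, "horizon"), use.names = FALSE)
  )
}

#' Remove training pairs whose target reverts to a less severe state
#'
#' Individual pairs (not whole patients) are dropped when the target visit's
#' label is less severe than the last prefix visit's label, using the
#' severity order Control < aMCI < AD.
#'
#' @param pairs an `lc_pairs` table.
#' @param x the `lc_cohort` the pairs index into.
#' @return the filtered `lc_pairs`.
#' @export
drop_reversion_pairs <- function(pairs, x) {
  if (!nrow(pairs)) return(pairs)
  last_prefix <- vapply(pairs$prefix_rows, function(r) r[length(r)], integer(1))
  rev <- label_severity(pairs$target_label) <
    label_severity(x$visits$label[last_prefix])
  pairs[!rev, , drop = FALSE]
}

#' Evaluation pair for the 3-10-year horizon
#'
#' For each patient the target is the *last* visit; the prefix consists of
#' every visit dated between `min_h` and `max_h` years before the target.
#' Prefix augmentation is not applied at evaluation time. Patients with no
#' qualifying prefix visit yield no pair, so each patient contributes zero
#' or one evaluation pair. The horizon is measured from the most recent
#' prefix visit to the target.
#'
#' @param x an `lc_cohort`.
#' @param min_h,max_h horizon window in years (inclusive).
#' @param patient_ids optional subset of patients.
#' @return an `lc_pairs` table with at most one row per patient.
#' @export
build_eval_pairs <- function(x, min_h = 3.0, max_h = 10.0, patient_ids = NULL) {
  stopifnot(inherits(x, "lc_cohort"))
  rows <- patient_rows(x)
  if (!is.null(patient_ids)) rows <- rows[names(rows) %in% patient_ids]
  out <- lapply(rows, function(idx) {
    t <- length(idx)
    if (t < 2L) return(NULL)
    target <- idx[t]
    back <- vapply(idx[-t], function(i) {
      years_between(x$visits$visit_date[i], x$visits$visit_date[target])
    }, numeric(1))
    sel <- idx[-t][back >= min_h & back <= max_h]
    if (!length(sel)) return(NULL)
    list(prefix = sel, target = target,
         horizon = years_between(x$visits$visit_date[sel[length(sel)]],
                                 x$visits$visit_date[target]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_pairs())
  tr <- vapply(out, `[[`, integer(1), "target")
  new_pairs(
    patient_id = names(out),
    prefix_rows = lapply(out, `[[`, "prefix"),
    target_row = tr,
    target_label = x$visits$label[tr],
    horizon_years = vapply(out, `[[`, numeric(1), "horizon")
  )
}

#' Patient-level k-fold assignment
#'
#' Patients (never individual samples) are assigned to folds so that all
#' pairs derived from one patient share a fold and train/validation patient
#' sets are disjoint in every fold. Patient ids are sorted, permuted with
#' the seeded RNG, and dealt round-robin, so fold sizes differ by at most
#' one patient.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return named integer vector: fold index (1..k) per patient id.
#' @export
split_folds <- function(patient_ids, k = 10L, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (k < 2L || k > n) stop_data("k must be in [2, number of patients]")
  with_seed(seed, {
    perm <- sample(sort(patient_ids))
    folds <- rep_len(seq_len(k), n)
    stats::setNames(folds[match(patient_ids, perm)], patient_ids)
  })
}

#' Prepare a cohort for modelling
#'
#' Convenience wrapper running the full data pipeline: eligibility
#' filtering, non-AD-dementia exclusion, patient-level class balancing by
#' final status, and patient-level fold assignment.
#'
#' @param x an `lc_cohort`.
#' @param k number of cross-validation folds.
#' @param seed integer RNG seed (balancing draw and fold permutation).
#' @param min_span,max_span,min_visits eligibility window, see
#'   [filter_eligibility()].
#' @return list with elements `cohort` (filtered + balanced), `folds`
#'   (named fold vector) and `final` (patient final-status table).
#' @export
prepare_cohort <- function(x, k = 10L, seed = 1L,
                           min_span = 3.0, max_span = 10.0, min_visits = 2L) {
  x <- drop_non_ad_and_reversions(x)
  x <- filter_eligibility(x, min_span, max_span, min_visits)
  fl <- final_labels(x)
  if (!nrow(fl)) stop_data("no eligible patients after filtering")
  keep <- balance_classes(fl$final_label, seed = seed)
  x <- subset_patients(x, fl$patient_id[keep])
  fl <- fl[keep, , drop = FALSE]
  folds <- split_folds(fl$patient_id, k = k, seed = seed)
  list(cohort = x, folds = folds, final = fl)
}
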