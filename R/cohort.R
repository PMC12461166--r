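#' Diagnostic label levels, ordered by severity
#'
#' The three predicted cognitive states, ordered from least to most severe.
#' `"OtherDementia"` may appear in raw input data and is handled (by patient
#' exclusion) in [drop_non_ad_and_reversions()]; it is never predicted.
#'
#' @export
LABEL_LEVELS <- c("Control", "aMCI", "AD")

label_severity <- function(labels) {
  sev <- match(labels, LABEL_LEVELS)
  if (anyNA(sev)) {
    bad <- unique(labels[is.na(sev)])
    stop_data("unknown diagnosis label(s): %s", paste(bad, collapse = ", "))
  }
  sev
}

#' Construct a feature specification table
#'
#' A feature specification describes every column of a longitudinal visit
#' table: its group (`"cognition"` for per-visit neuropsychological scores,
#' `"health"` for health/history variables), whether it is static (does not
#' change across a patient's visits, e.g. family history) and whether its raw
#' coding is strictly positive.
#'
#' @param name character vector of unique feature names.
#' @param group `"cognition"` or `"health"`, recycled.
#' @param static logical, recycled; static features are masked out of the
#'   "change" feature set because a constant ratio of 1 is uninformative.
#' @param positive_coding logical, recycled; `TRUE` means every non-missing
#'   raw value is `> 0`, the property the sentinel imputation relies on.
#' @return a `data.frame` of class `lc_feature_spec`.
#' @export
feature_spec <- function(name, group, static = FALSE, positive_coding = TRUE) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop_data("feature names must be unique")
  group <- rep_len(as.character(group), length(name))
  if (!all(group %in% c("cognition", "health"))) {
    stop_data("feature group must be 'cognition' or 'health'")
  }
  out <- data.frame(
    name = name,
    group = group,
    static = rep_len(as.logical(static), length(name)),
    positive_coding = rep_len(as.logical(positive_coding), length(name)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("lc_feature_spec", "data.frame")
  out
}

#' Generate a default feature specification
#'
#' Cognition features are named `cog01, cog02, ...`; health features
#' `hlt01, ...`. The last `n_static` health features are flagged static
#' (history-type variables). All features use positive coding.
#'
#' @param n_cognition,n_health counts of dynamic score features and
#'   health/history features.
#' @param n_static how many of the health features are static;
#'   must be `<= n_health`.
#' @return an `lc_feature_spec`.
#' @export
make_feature_spec <- function(n_cognition, n_health, n_static = 0L) {
  if (n_cognition < 1L || n_health < 0L) stop_data("feature counts must be positive")
  if (n_static > n_health) stop_data("n_static cannot exceed n_health")
  nm <- c(sprintf("cog%02d", seq_len(n_cognition)),
          if (n_health > 0L) sprintf("hlt%02d", seq_len(n_health)))
  grp <- c(rep("cognition", n_cognition), rep("health", n_health))
  st <- c(rep(FALSE, n_cognition), rep(FALSE, n_health - n_static), rep(TRUE, n_static))
  feature_spec(nm, grp, static = st)
}

#' Construct a longitudinal cohort object
#'
#' @param visits a data.frame with columns `patient_id`, `visit_date`
#'   (coercible to `Date`), `label` (one of `Control`, `aMCI`, `AD`, or
#'   `OtherDementia` in raw data) and one numeric column per feature in
#'   `features`. Missing measurements are `NA`.
#' @param features an [feature_spec()] table describing the feature columns.
#' @return an object of class `lc_cohort`: a list with elements `visits`
#'   (visit-level data.frame, ordered by patient then date) and `features`.
#' @export
cohort <- function(visits, features) {
  stopifnot(is.data.frame(visits))
  need <- c("patient_id", "visit_date", "label")
  if (!all(need %in% names(visits))) {
    stop_data("visit table must have columns %s", paste(need, collapse = ", "))
  }
  missing_feats <- setdiff(features$name, names(visits))
  if (length(missing_feats)) {
    stop_data("visit table lacks feature column(s): %s",
              paste(missing_feats, collapse = ", "))
  }
  visits$patient_id <- as.character(visits$patient_id)
  visits$visit_date <- as.Date(visits$visit_date)
  if (anyNA(visits$visit_date)) {
    bad <- unique(visits$patient_id[is.na(visits$visit_date)])
    stop_data("undated visit(s) for patient(s): %s", paste(bad, collapse = ", "))
  }
  visits <- visits[order(visits$patient_id, visits$visit_date), , drop = FALSE]
  rownames(visits) <- NULL
  structure(list(visits = visits, features = features), class = "lc_cohort")
}

#' @export
print.lc_cohort <- function(x, ...) {
  np <- length(unique(x$visits$patient_id))
  cat(sprintf("<lc_cohort> %d patients, %d visits, %d features (%d cognition / %d health, %d static)\n",
              np, nrow(x$visits), nrow(x$features),
              sum(x$features$group == "cognition"),
              sum(x$features$group == "health"),
              sum(x$features$static)))
  fl <- final_labels(x)
  print(table(factor(fl$final_label, levels = LABEL_LEVELS)))
  invisible(x)
}

#' Final diagnosis label per patient
#'
#' @param x an `lc_cohort`.
#' @return data.frame with `patient_id` and `final_label` (label of the
#'   patient's last visit).
#' @export
final_labels <- function(x) {
  v <- x$visits
  last <- !duplicated(v$patient_id, fromLast = TRUE)
  data.frame(patient_id = v$patient_id[last], final_label = v$label[last],
             stringsAsFactors = FALSE)
}

# split visit row indices by patient, preserving date order
patient_rows <- function(x) split(seq_len(nrow(x$visits)), x$visits$patient_id)

subset_patients <- function(x, ids) {
  keep <- x$visits$patient_id %in% ids
  cohort(x$visits[keep, , drop = FALSE], x$features)
}
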