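#' Write / read a cohort as long-format CSV with a feature-spec sidecar
#'
#' The visit table is written one row per visit with columns `patient_id`,
#' `visit_date` (ISO-8601), `label` and one column per feature; missing
#' cells are empty. The sidecar is a YAML file mapping each feature name to
#' its `group`, `static` and `positive_coding` flags.
#'
#' @param x an `lc_cohort`.
#' @param path CSV path for the visit table.
#' @param spec_path YAML path for the feature specification;
#'   defaults to `path` with a `.spec.yaml` extension.
#' @return `read_cohort_csv()` returns the `lc_cohort`.
#' @export
write_cohort_csv <- function(x, path, spec_path = NULL) {
  stopifnot(inherits(x, "lc_cohort"))
  spec_path <- spec_path %||% sub("\\.csv$", ".spec.yaml", path)
  v <- x$visits
  v$visit_date <- format(v$visit_date, "%Y-%m-%d")
  utils::write.csv(v, path, row.names = FALSE, na = "")
  write_feature_spec(x$features, spec_path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, spec_path = NULL) {
  spec_path <- spec_path %||% sub("\\.csv$", ".spec.yaml", path)
  spec <- read_feature_spec(spec_path)
  v <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  cohort(v, spec)
}

#' Write / read a feature specification as YAML
#'
#' @param spec an [feature_spec()].
#' @param path YAML file path.
#' @return `read_feature_spec()` returns the `lc_feature_spec`.
#' @export
write_feature_spec <- function(spec, path) {
  entries <- lapply(seq_len(nrow(spec)), function(i) {
    list(group = spec$group[i], static = spec$static[i],
         positive_coding = spec$positive_coding[i])
  })
  names(entries) <- spec$name
  yaml::write_yaml(list(features = entries), path)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  raw <- yaml::read_yaml(path)$features
  feature_spec(
    name = names(raw),
    group = vapply(raw, `[[`, character(1), "group"),
    static = vapply(raw, `[[`, logical(1), "static"),
    positive_coding = vapply(raw, `[[`, logical(1), "positive_coding")
  )
}

#' Write a pairs manifest CSV
#'
#' One row per (prefix, target) pair: `patient_id`, `pair_index`,
#' `prefix_visit_dates` (semicolon-separated ISO dates), `target_date`,
#' `target_label`, `horizon_years`, plus `fold` when a fold assignment is
#' supplied.
#'
#' @param pairs an `lc_pairs` table.
#' @param x the `lc_cohort` the pairs index into.
#' @param path output CSV path.
#' @param folds optional named fold vector from [split_folds()].
#' @export
write_pairs_manifest <- function(pairs, x, path, folds = NULL) {
  d <- x$visits$visit_date
  out <- data.frame(
    patient_id = pairs$patient_id,
    pair_index = stats::ave(seq_len(nrow(pairs)), pairs$patient_id,
                            FUN = seq_along),
    prefix_visit_dates = vapply(pairs$prefix_rows, function(r) {
      paste(format(d[r], "%Y-%m-%d"), collapse = ";")
    }, character(1)),
    target_date = format(d[pairs$target_row], "%Y-%m-%d"),
    target_label = pairs$target_label,
    horizon_years = pairs$horizon_years,
    stringsAsFactors = FALSE
  )
  if (!is.null(folds)) out$fold <- unname(folds[out$patient_id])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint as a single JSON file
#'
#' Stores the configuration, the feature count and every weight array
#' (with shapes) in one text file.
#'
#' @param model an [init_model()] (possibly trained) object.
#' @param path JSON file path.
#' @return `read_model()` returns the `lc_model`.
#' @export
write_model <- function(model, path) {
  ser <- function(p) {
    if (is.list(p)) lapply(p, ser)
    else if (is.matrix(p)) list(.dim = dim(p), .data = as.numeric(p))
    else list(.dim = length(p), .data = as.numeric(p))
  }
  obj <- list(config = unclass(model$config), n_features = model$n_features,
              params = ser(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(p) {
    if (is.list(p) && !is.null(p$.data)) {
      dm <- as.integer(unlist(p$.dim))
      x <- as.numeric(unlist(p$.data))
      if (length(dm) == 2L) matrix(x, dm[1], dm[2]) else x
    } else {
      lapply(p, de)
    }
  }
  cfg <- do.call(model_config, obj$config[c("imputation", "hidden_size",
                                            "heads", "transformer_layers",
                                            "lstm_layers", "dropout",
                                            "n_classes", "sentinel")])
  structure(list(config = cfg, n_features = as.integer(obj$n_features),
                 params = de(obj$params)),
            class = "lc_model")
}
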