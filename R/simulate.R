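#' Simulation configuration for synthetic longitudinal cohorts
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The generator emulates the structure of a multi-center longitudinal
#' dementia registry: multi-year visit records with approximately annual
#' visits, per-visit cognitive scores, largely static health/history
#' variables, strictly positive raw coding, cell-level missingness, and
#' three outcome trajectories (stable control, conversion to aMCI,
#' conversion to AD).
#'
#' @param n_patients number of patients to simulate.
#' @param n_cognition,n_health,n_static feature counts, see
#'   [make_feature_spec()].
#' @param class_mix length-3 numeric summing to 1: proportions of
#'   stable-control, converts-to-aMCI and converts-to-AD trajectories.
#' @param effect_size mean trajectory separation in control-SD units:
#'   converters-to-AD drift downward in cognition features by
#'   `effect_size` SD between their first and last visit (aMCI converters
#'   by half that), and converters carry proportionally shifted baseline
#'   cognition and static risk features. `0` gives a null cohort whose
#'   features are independent of labels.
#' @param missing_rate per-cell missingness probability (MCAR), in `[0, 1)`.
#' @param visits_per_patient integer range `c(min, max)` of visits.
#' @param span_years numeric range of first-to-last visit spans, a subset
#'   of `(0, 12]`. The default deliberately covers both eligible (3-10 y)
#'   and ineligible spans so the eligibility filter is exercised.
#' @param seed integer RNG seed; identical configurations with identical
#'   seeds generate identical cohorts.
#' @return a validated list of class `lc_sim_config`.
#' @export
simulation_config <- function(n_patients = 300L,
                              n_cognition = 8L,
                              n_health = 6L,
                              n_static = 3L,
                              class_mix = c(1, 1, 1) / 3,
                              effect_size = 1.0,
                              missing_rate = 0.1,
                              visits_per_patient = c(2L, 8L),
                              span_years = c(1, 11),
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_cognition = as.integer(n_cognition),
    n_health = as.integer(n_health), n_static = as.integer(n_static),
    class_mix = as.numeric(class_mix), effect_size = as.numeric(effect_size),
    missing_rate = as.numeric(missing_rate),
    visits_per_patient = as.integer(visits_per_patient),
    span_years = as.numeric(span_years), seed = as.integer(seed)
  )
  if (cfg$n_patients < 1L) stop_data("n_patients must be >= 1")
  if (cfg$n_cognition < 1L) stop_data("n_cognition must be >= 1")
  if (length(cfg$class_mix) != 3L || any(cfg$class_mix < 0) ||
      abs(sum(cfg$class_mix) - 1) > 1e-8) {
    stop_data("class_mix must be 3 non-negative proportions summing to 1")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_data("missing_rate must be in [0, 1)")
  }
  if (length(cfg$visits_per_patient) != 2L || cfg$visits_per_patient[1] < 2L ||
      diff(cfg$visits_per_patient) < 0L) {
    stop_data("visits_per_patient must be an increasing range with min >= 2")
  }
  if (length(cfg$span_years) != 2L || cfg$span_years[1] <= 0 ||
      cfg$span_years[2] > 12 || diff(cfg$span_years) < 0) {
    stop_data("span_years must be an increasing range within (0, 12]")
  }
  class(cfg) <- "lc_sim_config"
  cfg
}

# Per-feature population parameters of the generator. Raw values are
# shifted log-normal (always > 0); `sd` is the nominal control-population
# SD used to express class separation in SD units.
sim_feature_params <- function(spec) {
  K <- nrow(spec)
  mu <- 6 + 9 * (seq_len(K) - 1) %% 7        # population scale, spread over features
  data.frame(
    name = spec$name,
    mu = mu,
    sd = 0.17 * mu,                          # nominal control SD
    stringsAsFactors = FALSE
  )
}

# severity weight of a trajectory class: how strongly its features separate
# from controls (aMCI trajectories generated intermediate between the others)
class_weight <- function(cls) c(Control = 0, aMCI = 0.5, AD = 1)[[cls]]

#' Simulate a synthetic longitudinal cohort
#'
#' Deterministic given `(config, seed)`. Converter trajectories follow a
#' change-point model: visits before the (random) conversion visit are
#' labelled `Control`; from that visit on, the label is the converted state
#' (AD converters may pass through an intermediate aMCI stage). Cognition
#' features of converters carry a constant prodromal downward shift at all
#' visits plus a linear-in-time downward drift after the change point,
#' scaled so the first-to-last drift equals `effect_size` control-SD for AD
#' converters (half for aMCI). Static health features of converters are
#' shifted upward (elevated risk factors). All raw values stay strictly
#' positive. Cell-level MCAR missingness is applied at `config$missing_rate`.
#'
#' @param config an [simulation_config()].
#' @return an [cohort()] object.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "lc_sim_config"))
  spec <- make_feature_spec(config$n_cognition, config$n_health, config$n_static)
  fp <- sim_feature_params(spec)
  K <- nrow(spec)
  with_seed(config$seed, {
    classes <- sample(LABEL_LEVELS, config$n_patients, replace = TRUE,
                      prob = config$class_mix)
    recs <- vector("list", config$n_patients)
    for (p in seq_len(config$n_patients)) {
      recs[[p]] <- simulate_patient(sprintf("P%05d", p), classes[p], spec, fp, config)
    }
    visits <- do.call(rbind, recs)
    ch <- cohort(visits, spec)
    if (config$missing_rate > 0) {
      # draws from the same seeded stream; labels/dates never dropped
      ch <- apply_mcar(ch, config$missing_rate)
    }
    attr(ch, "sim_truth") <- fp
    ch
  })
}

simulate_patient <- function(pid, cls, spec, fp, config) {
  nv <- sample(seq(config$visits_per_patient[1], config$visits_per_patient[2]), 1L)
  span <- runif(1, config$span_years[1], config$span_years[2])
  # approximately annual gaps, rescaled to the drawn span
  if (nv == 2L) {
    times <- c(0, span)
  } else {
    gaps <- runif(nv - 1L, 0.8, 1.5)
    times <- c(0, cumsum(gaps)) * span / sum(gaps)
  }
  start <- as.Date("2008-01-01") + sample(0:3652, 1L)
  d <- as.integer(round(times * 365.25))
  # enforce strictly increasing dates after rounding to whole days
  if (nv > 1L) for (i in 2:nv) if (d[i] <= d[i - 1L]) d[i] <- d[i - 1L] + 1L
  dates <- start + d
  times <- d / 365.25

  w <- class_weight(cls)
  # change-point structure: first visit index carrying a non-Control label
  labels <- rep("Control", nv)
  if (cls == "aMCI") {
    cp <- sample(2:nv, 1L)
    labels[cp:nv] <- "aMCI"
  } else if (cls == "AD") {
    cp_ad <- sample(2:nv, 1L)
    cp <- if (cp_ad > 1L) sample(seq_len(cp_ad), 1L) else 1L
    labels[cp:nv] <- "aMCI"
    labels[cp_ad:nv] <- "AD"
  } else {
    cp <- NA_integer_
  }
  # drift progress: 0 before the change point, ramping to 1 at the last visit
  progress <- rep(0, nv)
  if (!is.na(cp)) {
    t_cp <- times[cp]
    denom <- times[nv] - t_cp
    if (denom > 0) {
      progress <- pmax(0, (times - t_cp) / denom)
    } else {
      progress[nv] <- 1   # change point at the last visit
    }
  }

  es <- config$effect_size
  vals <- matrix(NA_real_, nrow = nv, ncol = nrow(spec),
                 dimnames = list(NULL, spec$name))
  for (j in seq_len(nrow(spec))) {
    mu <- fp$mu[j]; sdj <- fp$sd[j]
    if (spec$static[j]) {
      # constant within patient; converters carry elevated risk coding
      v <- 0.5 + stats::rlnorm(1, meanlog = log(mu), sdlog = 0.15) +
        0.4 * es * sdj * w
      vals[, j] <- v
    } else {
      base <- 0.5 + stats::rlnorm(1, meanlog = log(mu), sdlog = 0.15)
      noise <- exp(stats::rnorm(nv, 0, 0.08))
      x <- base * noise
      if (spec$group[j] == "cognition" && w > 0) {
        # converters: constant prodromal shift, slow decline from the first
        # visit (pathology precedes diagnosis), and accelerated decline
        # after the change point; first-to-last drift totals es * SD * w
        early <- (times - times[1]) / max(times[nv] - times[1], 1e-9)
        x <- x - 0.5 * es * sdj * w -
          0.5 * es * sdj * w * early -
          0.5 * es * sdj * w * progress
      }
      vals[, j] <- pmax(x, 0.02 * mu)   # preserve strictly positive coding
    }
  }
  out <- data.frame(patient_id = pid, visit_date = dates, label = labels,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vals))
}

apply_mcar <- function(ch, rate) {
  feats <- ch$features$name
  m <- as.matrix(ch$visits[feats])
  drop <- matrix(stats::runif(length(m)) < rate, nrow = nrow(m))
  m[drop] <- NA_real_
  ch$visits[feats] <- as.data.frame(m)
  ch
}

#' Simulate a matched null cohort
#'
#' Same generator and visit/label structure as [simulate_cohort()] but with
#' `effect_size` forced to 0, so labels are independent of every feature.
#' Used to verify that trained models achieve only chance-level accuracy in
#' the absence of signal.
#'
#' @inheritParams simulate_cohort
#' @return an [cohort()] object.
#' @export
null_cohort <- function(config) {
  stopifnot(inherits(config, "lc_sim_config"))
  config$effect_size <- 0
  simulate_cohort(config)
}

#' Inject additional missingness into a cohort
#'
#' `MCAR` drops every feature cell independently with probability `rate`.
#' `visit_block` additionally drops, with probability `rate` per
#' patient-feature, that feature at *all* of the patient's visits —
#' emulating measurements systematically absent for a given participant.
#' Labels and visit dates are never dropped.
#'
#' @param x an `lc_cohort`.
#' @param rate probability in `[0, 1)`; `rate = 0` returns `x` unchanged.
#' @param mechanism `"MCAR"` or `"visit_block"`.
#' @param seed integer RNG seed.
#' @return an `lc_cohort` with additional `NA` cells.
#' @export
inject_missingness <- function(x, rate, mechanism = c("MCAR", "visit_block"),
                               seed = 1L) {
  stopifnot(inherits(x, "lc_cohort"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate > 1) stop_data("rate must be in [0, 1]")
  if (rate >= 1 && mechanism == "MCAR") stop_data("MCAR rate must be < 1")
  if (rate == 0) return(x)
  with_seed(seed, {
    feats <- x$features$name
    m <- as.matrix(x$visits[feats])
    if (mechanism == "MCAR") {
      m[matrix(stats::runif(length(m)) < rate, nrow = nrow(m))] <- NA_real_
    } else {
      pid <- x$visits$patient_id
      for (id in unique(pid)) {
        rows <- which(pid == id)
        blocked <- stats::runif(length(feats)) < rate
        m[rows, blocked] <- NA_real_
      }
      m[matrix(stats::runif(length(m)) < min(rate, 1 - 1e-12), nrow = nrow(m))] <- NA_real_
    }
    x$visits[feats] <- as.data.frame(m)
    x
  })
}
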