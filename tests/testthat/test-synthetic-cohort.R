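test_that("simulation is deterministic and respects class mix", {
  cfg <- simulation_config(n_patients = 300L, class_mix = c(1, 1, 1) / 3,
                           seed = 7L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)

  counts <- table(factor(final_labels(a)$final_label, levels = LABEL_LEVELS))
  # multinomial sampling error: 100 +/- ~4 SD
  expect_true(all(abs(counts - 100) < 35))

  c2 <- simulate_cohort(simulation_config(n_patients = 300L, seed = 8L))
  expect_false(identical(a$visits$cog01, c2$visits$cog01))
})

test_that("raw coding is strictly positive and static features are constant", {
  ch <- simulate_cohort(simulation_config(n_patients = 80L, seed = 3L))
  m <- as.matrix(ch$visits[ch$features$name])
  expect_gt(min(m, na.rm = TRUE), 0)
  for (f in ch$features$name[ch$features$static]) {
    per_pat <- tapply(ch$visits[[f]], ch$visits$patient_id,
                      function(v) length(unique(v[!is.na(v)])))
    expect_true(all(per_pat <= 1L))
  }
})

test_that("visit dates strictly increase and labels never revert", {
  ch <- simulate_cohort(simulation_config(n_patients = 120L, seed = 9L))
  for (idx in split(seq_len(nrow(ch$visits)), ch$visits$patient_id)) {
    d <- ch$visits$visit_date[idx]
    expect_true(all(diff(as.numeric(d)) > 0))
    sev <- match(ch$visits$label[idx], LABEL_LEVELS)
    expect_true(all(diff(sev) >= 0))
  }
})

test_that("converter cognition features drift by effect_size SD, monotonically", {
  drift_of <- function(es, seed = 21L) {
    cfg <- simulation_config(n_patients = 250L, effect_size = es,
                             missing_rate = 0, seed = seed)
    ch <- simulate_cohort(cfg)
    truth <- attr(ch, "sim_truth")
    fl <- final_labels(ch)
    ad <- fl$patient_id[fl$final_label == "AD"]
    cogs <- ch$features$name[ch$features$group == "cognition"]
    drifts <- sapply(cogs, function(f) {
      per <- tapply(ch$visits[[f]][ch$visits$patient_id %in% ad],
                    ch$visits$patient_id[ch$visits$patient_id %in% ad],
                    function(v) v[1] - v[length(v)])
      mean(per) / truth$sd[truth$name == f]
    })
    mean(drifts)
  }
  d <- vapply(c(0.5, 1, 2), drift_of, numeric(1))
  # first-to-last decline in SD units matches the configured effect size
  expect_equal(d, c(0.5, 1, 2), tolerance = 0.12)
  expect_true(all(diff(d) > 0))
})

test_that("null construction: no systematic first-visit differences at effect 0", {
  cfg <- simulation_config(n_patients = 400L, effect_size = 0,
                           missing_rate = 0, seed = 5L)
  ch <- simulate_cohort(cfg)
  fl <- final_labels(ch)
  first <- ch$visits[!duplicated(ch$visits$patient_id), ]
  grp <- fl$final_label[match(first$patient_id, fl$patient_id)]
  pvals <- vapply(ch$features$name, function(f) {
    stats::t.test(first[[f]][grp == "Control"], first[[f]][grp == "AD"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("null_cohort zeroes the effect but keeps structure", {
  cfg <- simulation_config(n_patients = 50L, effect_size = 2, seed = 13L)
  nc <- null_cohort(cfg)
  expect_s3_class(nc, "lc_cohort")
  # same visit scaffolding (dates, patients) as the matched effect-0 cohort
  cfg0 <- cfg; cfg0$effect_size <- 0
  expect_identical(nc$visits, simulate_cohort(cfg0)$visits)
  expect_identical(nc$visits, null_cohort(cfg)$visits)
})

test_that("inject_missingness: identity, rate, and block mechanisms", {
  ch <- simulate_cohort(simulation_config(n_patients = 170L, missing_rate = 0,
                                          seed = 2L))
  expect_identical(inject_missingness(ch, 0), ch)

  mc <- inject_missingness(ch, 0.3, "MCAR", seed = 4L)
  m <- as.matrix(mc$visits[mc$features$name])
  expect_gt(length(m), 10000L)   # binomial SE < 0.005 at this cell count
  expect_lt(abs(mean(is.na(m)) - 0.3), 0.02)
  expect_false(anyNA(mc$visits$label))
  expect_false(anyNA(mc$visits$visit_date))

  vb <- inject_missingness(ch, 1, "visit_block", seed = 4L)
  expect_true(all(is.na(as.matrix(vb$visits[vb$features$name]))))

  vb2 <- inject_missingness(ch, 0.2, "visit_block", seed = 4L)
  # block mechanism leaves whole patient-feature series missing
  blocked <- tapply(vb2$visits$cog01, vb2$visits$patient_id,
                    function(v) all(is.na(v)))
  expect_gt(sum(blocked), 0)

  expect_error(inject_missingness(ch, 1.2), "rate")
  expect_error(inject_missingness(ch, 1, "MCAR"), "rate")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(class_mix = c(0.5, 0.5, 0.5)), "class_mix")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(span_years = c(0, 13)), "span_years")
  expect_error(simulation_config(n_cognition = 0), "n_cognition")
  expect_error(simulation_config(visits_per_patient = c(1, 5)), "visits_per_patient")
})
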