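make_ctrl_stats <- function(mean, sd, flagged = character(0)) {
  structure(list(mean = mean, sd = sd, n_control = 10L, flagged = flagged),
            class = "lc_control_stats")
}

test_that("control stats use sample sd over observed control visits only", {
  ch <- hand_cohort(list(
    A = list(years = c(0, 1, 2), labels = rep("Control", 3)),
    B = list(years = c(0, 1, 2), labels = rep("Control", 3)),
    C = list(years = c(0, 4), labels = c("Control", "AD"))
  ))
  # plant known values: controls A,B hold {1,2,3} x 2 on cog01
  ch$visits$cog01 <- c(1, 2, 3, 1, 2, 3, 100, 100)
  st <- fit_control_stats(ch, c("A", "B", "C"))
  expect_equal(unname(st$mean["cog01"]), 2)
  expect_equal(unname(st$sd["cog01"]), stats::sd(c(1, 2, 3, 1, 2, 3)))
  expect_equal(st$n_control, 2L)

  # all-missing feature is flagged and passes through as missing
  ch$visits$cog02[ch$visits$patient_id %in% c("A", "B")] <- NA
  st2 <- fit_control_stats(ch, c("A", "B", "C"))
  expect_true("cog02" %in% st2$flagged)
  z <- zscore_baseline(c(cog01 = 5, cog02 = 1), st2)
  expect_true(is.na(z$baseline["cog02"]))
  expect_equal(unname(z$mask), c(1, 0))

  expect_error(fit_control_stats(ch, "C"), ">= 2 control")
})

test_that("z-scoring matches (x - mean)/sd and keeps missing masked", {
  st <- make_ctrl_stats(c(f1 = 3, f2 = 0), c(f1 = 2, f2 = 1))
  z <- zscore_baseline(c(f1 = 5, f2 = NA), st)
  expect_equal(unname(z$baseline["f1"]), 1.0)
  expect_true(is.na(z$baseline["f2"]))
  expect_equal(unname(z$mask), c(1, 0))
  # identity stats leave values unchanged (idempotence under identity)
  ident <- make_ctrl_stats(c(f1 = 0, f2 = 0), c(f1 = 1, f2 = 1))
  v <- c(f1 = 1.7, f2 = -0.3)
  expect_equal(zscore_baseline(v, ident)$baseline, v)
})

test_that("control training population re-scores to mean 0, sd 1", {
  ch <- simulate_cohort(simulation_config(n_patients = 800L, missing_rate = 0.05,
                                          seed = 19L))
  ids <- unique(ch$visits$patient_id)
  st <- fit_control_stats(ch, ids)
  fl <- final_labels(ch)
  ctrl_rows <- ch$visits$patient_id %in% fl$patient_id[fl$final_label == "Control"]
  for (f in ch$features$name[1:4]) {
    zs <- (ch$visits[[f]][ctrl_rows] - st$mean[f]) / st$sd[f]
    zs <- zs[!is.na(zs)]
    expect_gt(length(zs), 1000L)
    expect_lt(abs(mean(zs)), 0.01)
    expect_lt(abs(stats::sd(zs) - 1), 0.01)
  }
})

test_that("change ratios are raw-value ratios with a unit first column", {
  m <- rbind(f1 = c(2, 3, 5), f2 = c(4, NA, 2), f3 = c(0, 1, 1), f4 = c(NA, 1, 1))
  ch <- change_ratios(m)
  expect_equal(unname(ch$change["f1", ]), c(1, 1.5, 2.5))
  expect_equal(unname(ch$change["f2", c(1, 3)]), c(1, 0.5))
  expect_true(is.na(ch$change["f2", 2]))
  # zero and missing denominators mask the whole row
  expect_true(all(ch$mask["f3", ] == 0))
  expect_true(all(ch$mask["f4", ] == 0))
  # first column is 1 wherever defined
  obs1 <- ch$mask[, 1] == 1
  expect_true(all(ch$change[obs1, 1] == 1))
})

test_that("static features are masked in change but kept in baseline", {
  spec <- feature_spec(c("f1", "fh"), c("cognition", "health"),
                       static = c(FALSE, TRUE))
  m <- rbind(f1 = c(2, 4), fh = c(1, 1))
  ch <- mask_static_in_change(change_ratios(m), spec)
  expect_true(all(ch$mask["fh", ] == 0))
  expect_equal(unname(ch$change["f1", ]), c(1, 2))
})

test_that("engineered samples carry masks that never add observations", {
  ch <- simulate_cohort(simulation_config(n_patients = 60L, missing_rate = 0.2,
                                          seed = 29L))
  ids <- unique(ch$visits$patient_id)
  st <- fit_control_stats(ch, ids)
  pairs <- augment_prefixes(ch)
  for (i in seq_len(min(nrow(pairs), 25L))) {
    s <- engineer_sample(pairs[i, ], ch, st)
    prefix <- pairs$prefix_rows[[i]]
    raw <- t(as.matrix(ch$visits[prefix, ch$features$name]))
    # baseline mask subset of last-visit observations
    expect_true(all(s$baseline_mask <= as.numeric(!is.na(raw[, ncol(raw)]))))
    # change mask subset of raw observations
    expect_true(all(s$change_mask <= (!is.na(raw)) * 1))
    # first change column is 1 where observed
    obs1 <- s$change_mask[, 1] == 1
    if (any(obs1)) expect_true(all(s$change[obs1, 1] == 1))
    # static rows fully masked in change
    expect_true(all(s$change_mask[ch$features$static, ] == 0))
  }
})

test_that("control stats round-trip through JSON", {
  st <- make_ctrl_stats(c(a = 1.5, b = NA), c(a = 2.25, b = NA), flagged = "b")
  p <- withr::local_tempfile(fileext = ".json")
  write_control_stats(st, p)
  st2 <- read_control_stats(p)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)
  expect_equal(st2$flagged, "b")
  expect_equal(st2$n_control, 10L)
})
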