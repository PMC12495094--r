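test_that("identical config and seed reproduce the cohort exactly", {
  c1 <- tiny_cohort(seed = 61, n_subjects = 6)
  c2 <- tiny_cohort(seed = 61, n_subjects = 6)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[2]]$ts_baseline, c2$subjects[[2]]$ts_baseline)
})

test_that("attrition removes exactly the configured fraction of 3-month scans", {
  coh <- generate_cohort(cohort_config(n_subjects = 50, n_regions = 6,
                                       n_timepoints = 30,
                                       attrition_fraction = 0.3, seed = 62))
  with_scan <- sum(!vapply(coh$subjects,
                           function(s) is.null(s$ts_followup), logical(1)))
  expect_equal(with_scan, 35)
  expect_equal(nrow(cohort_features(coh, "delta_fc")), 35)
  expect_equal(nrow(cohort_features(coh, "baseline_fc")), 50)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(effect_r2 = 0.5, n_causal_edges = 0), "causal")
  expect_error(cohort_config(effect_r2 = 1.2), "effect_r2")
  expect_error(cohort_config(attrition_fraction = -0.1), "attrition")
  expect_error(cohort_config(n_timepoints = 2), "n_timepoints")
  expect_error(cohort_config(n_regions = 4, n_causal_edges = 10),
               "n_causal_edges")
  # a pure-noise cohort needs no causal edges
  expect_s3_class(cohort_config(effect_r2 = 0, n_causal_edges = 0),
                  "cohort_config")
})

test_that("planted targets are exact and the effect size is calibrated", {
  coh <- tiny_cohort(seed = 63, n_subjects = 24, attrition_fraction = 0)
  expect_equal(sum(coh$truth$w != 0), coh$config$n_causal_edges)
  for (sc in c("SOFAS", "BPRS")) for (tp in c(6, 12)) {
    measure <- if (sc == "SOFAS") "functioning" else "symptoms"
    y <- build_targets(coh$outcomes, measure, tp)
    tr <- coh$truth$targets
    tr <- tr[tr$scale == sc & tr$visit_month == tp, ]
    expect_equal(unname(y[tr$subject_id]), tr$change, tolerance = 1e-12)
  }

  # calibration: mean squared target-signal correlation tracks effect_r2
  r2 <- vapply(1:60, function(i) {
    coh <- generate_cohort(cohort_config(n_subjects = 30, n_regions = 6,
                                         n_timepoints = 40, effect_r2 = 0.5,
                                         n_causal_edges = 3,
                                         attrition_fraction = 0,
                                         seed = 6300 + i))
    tr <- coh$truth$targets
    tr <- tr[tr$scale == "SOFAS" & tr$visit_month == 6, ]
    cor(tr$change, coh$truth$signal)^2
  }, numeric(1))
  expect_equal(mean(r2), 0.5, tolerance = 0.05)
})

test_that("null cohorts carry no target-signal association beyond chance", {
  n <- 20
  exceed <- vapply(1:100, function(i) {
    coh <- generate_cohort(cohort_config(n_subjects = n, n_regions = 6,
                                         n_timepoints = 40, effect_r2 = 0,
                                         n_causal_edges = 3,
                                         attrition_fraction = 0,
                                         seed = 6400 + i))
    tr <- coh$truth$targets
    tr <- tr[tr$scale == "SOFAS" & tr$visit_month == 6, ]
    r <- cor(tr$change, coh$truth$signal)
    abs(r) > tanh(1.96 / sqrt(n - 3))  # two-sided 95% null bound
  }, logical(1))
  # exceedances ~ Binomial(100, 0.05); reject only far outside that
  expect_lte(sum(exceed), qbinom(0.995, 100, 0.05))
})

test_that("scale scores respect their bounds and the item table is coherent", {
  coh <- tiny_cohort(seed = 65, n_subjects = 30, change_sd = 0.6)
  sofas <- coh$outcomes[coh$outcomes$scale == "SOFAS", "score"]
  bprs <- coh$outcomes[coh$outcomes$scale == "BPRS", "score"]
  expect_true(all(sofas >= 0 & sofas <= 100))
  expect_true(all(bprs >= 24 & bprs <= 168))
  expect_true(all(coh$bprs_items$score >= 1 - 1e-9 &
                    coh$bprs_items$score <= 7 + 1e-9))
  expect_equal(nrow(coh$bprs_items), 30 * 3 * 24)
  # item sums reproduce the recorded totals
  tot <- aggregate(score ~ subject_id + visit_month, coh$bprs_items, sum)
  rec <- coh$outcomes[coh$outcomes$scale == "BPRS", ]
  m <- merge(tot, rec, by = c("subject_id", "visit_month"))
  expect_equal(m$score.x, m$score.y, tolerance = 1e-9)
})

test_that("export and reload preserve the data exactly", {
  coh <- tiny_cohort(seed = 66, n_subjects = 3, n_regions = 5,
                     n_timepoints = 20, attrition_fraction = 1 / 3)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  export_cohort(coh, out)
  expect_error(export_cohort(coh, out), "force")

  # 2 subjects with both scans + 1 baseline-only = 5 time-series files
  expect_length(list.files(out, pattern = "\\.tsv$"), 5)
  expect_true(file.exists(file.path(out, "outcomes.csv")))

  back <- load_cohort(out)
  expect_named(back$outcomes,
               c("subject_id", "arm", "scale", "visit_month", "score"))
  expect_setequal(unique(back$outcomes$visit_month), c(0, 6, 12))
  expect_setequal(unique(back$outcomes$scale), c("SOFAS", "BPRS"))
  expect_equal(back$outcomes$score,
               coh$outcomes$score, tolerance = 0)

  # FC computed from the reloaded series matches the original exactly
  for (id in names(back$timeseries)) {
    orig <- Filter(function(s) s$id == id, coh$subjects)[[1]]
    expect_equal(compute_fc(back$timeseries[[id]]$baseline)$values,
                 compute_fc(orig$ts_baseline)$values, tolerance = 0)
  }

  # byte-identical re-export under the same config and seed
  coh2 <- tiny_cohort(seed = 66, n_subjects = 3, n_regions = 5,
                      n_timepoints = 20, attrition_fraction = 1 / 3)
  out2 <- file.path(dir, "cohort2")
  export_cohort(coh2, out2)
  f1 <- list.files(out, full.names = TRUE)
  f2 <- list.files(out2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
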