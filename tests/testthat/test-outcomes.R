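test_that("proportional change is the anchored ratio and is scale invariant", {
  expect_equal(proportional_change(50, 60), 0.20)
  for (y in c(1, 13.5, 100)) expect_equal(proportional_change(y, y), 0)
  # change of the group means: (42.6 - 57.8) / 57.8
  expect_equal(proportional_change(57.8, 42.6), -0.2629757785467128,
               tolerance = 1e-12)
  expect_error(proportional_change(0, 10), "undefined")
  set.seed(1)
  for (i in 1:20) {
    y1 <- runif(1, 10, 90); y2 <- runif(1, 10, 90); c0 <- runif(1, 0.1, 10)
    expect_equal(proportional_change(c0 * y1, c0 * y2),
                 proportional_change(y1, y2), tolerance = 1e-12)
  }
})

test_that("slope outcomes equal the closed-form OLS slope", {
  expect_equal(slope_outcome(c(0, 6, 12), c(50, 60, 70)), 5 / 3)
  expect_equal(slope_outcome(c(0, 6, 12), c(44, 44, 44)), 0)
  set.seed(2)
  for (i in 1:10) {
    t <- c(0, 6, 12); y <- rnorm(3, 50, 10)
    oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_equal(slope_outcome(t, y), oracle, tolerance = 1e-12)
  }
  # missing middle visit still fits on 2 points
  expect_equal(slope_outcome(c(0, 6, 12), c(50, NA, 62)), 1)
  expect_error(slope_outcome(c(0), c(50)), "at least 2")
  expect_error(slope_outcome(c(6, 6), c(50, 60)), "at least 2")
})

test_that("positive-symptom score sums exactly the four named items", {
  full <- setNames(rep(1, 24), bprs_item_names)
  expect_equal(positive_symptom_score(full), 4)
  expect_equal(positive_symptom_score(full + 6), 28)
  x <- full
  x[c("unusual_thought_content", "conceptual_disorganization",
      "hallucinations", "grandiosity")] <- c(3, 2, 5, 1)
  x["anxiety"] <- 7  # a non-positive item must not contribute
  expect_equal(positive_symptom_score(x), 11)
  expect_error(positive_symptom_score(full[-which(names(full) == "grandiosity")]),
               "grandiosity")
})

test_that("build_targets composes scores, drops incomplete subjects, never imputes", {
  tab <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 3),
    arm = rep(c("placebo", "medication", "placebo"), each = 3),
    scale = "SOFAS",
    visit_month = rep(c(0, 6, 12), 3),
    score = c(50, 60, 70, 40, 50, NA, 80, 72, 60))
  y6 <- build_targets(tab, "functioning", 6)
  expect_equal(unname(y6[c("s1", "s2", "s3")]), c(0.2, 0.25, -0.1))
  expect_equal(attr(y6, "n_total"), 3)

  # subject missing the 12-month score is excluded and logged
  y12 <- build_targets(tab, "functioning", 12)
  expect_false("s2" %in% names(y12))
  expect_equal(attr(y12, "dropped"), "s2")
  expect_lte(length(y12), 3)

  # slope path uses available visits (2 points for s2)
  ysl <- build_targets(tab, "functioning", 6, "slope")
  expect_equal(unname(ysl["s2"]), 10 / 6)
  expect_equal(unname(ysl["s1"]), 5 / 3)

  # arm filter applied before target construction
  yp <- build_targets(tab, "functioning", 6, arm = "placebo")
  expect_setequal(names(yp), c("s1", "s3"))

  expect_error(build_targets(tab, "symptoms", 6), "no subjects")
})

test_that("positive-symptom change targets come from the item-level table", {
  coh <- tiny_cohort(seed = 31, n_subjects = 10, attrition_fraction = 0)
  y <- build_targets(coh$outcomes, "symptoms", 6, "positive_change",
                     items = coh$bprs_items)
  expect_equal(length(y), 10)
  # cross-check one subject by hand
  sid <- names(y)[1]
  it <- coh$bprs_items
  s0 <- it[it$subject_id == sid & it$visit_month == 0, ]
  s6 <- it[it$subject_id == sid & it$visit_month == 6, ]
  p0 <- positive_symptom_score(setNames(s0$score, s0$item))
  p6 <- positive_symptom_score(setNames(s6$score, s6$item))
  expect_equal(unname(y[sid]), (p6 - p0) / p0, tolerance = 1e-12)
  expect_error(build_targets(coh$outcomes, "symptoms", 6, "positive_change"),
               "item-level")
  expect_error(build_targets(coh$outcomes, "functioning", 6, "positive_change",
                             items = coh$bprs_items), "symptoms")
})

test_that("outcome tables are validated against scale bounds and duplicates", {
  bad <- data.frame(subject_id = "s1", arm = "placebo", scale = "SOFAS",
                    visit_month = c(0, 0), score = c(50, 60))
  expect_error(build_targets(bad, "functioning", 6), "one score")
  oob <- data.frame(subject_id = "s1", arm = "placebo", scale = "BPRS",
                    visit_month = c(0, 6), score = c(20, 50))
  expect_error(build_targets(oob, "symptoms", 6), "24")
})
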