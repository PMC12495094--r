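# Shared fixture builders: small seeded cohorts and feature/target pairs.

tiny_cohort <- function(seed = 1L, n_subjects = 20L, n_regions = 8L,
                        n_timepoints = 60L, effect_r2 = 0.5,
                        n_causal_edges = 3L, attrition_fraction = 0.3, ...) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_regions = n_regions,
    n_timepoints = n_timepoints, effect_r2 = effect_r2,
    n_causal_edges = n_causal_edges,
    attrition_fraction = attrition_fraction, seed = seed, ...))
}

# Feature matrix and aligned functioning/6-month targets.
cohort_xy <- function(cohort, measure = "functioning", timepoint = 6,
                      predictor = "baseline_fc") {
  X <- cohort_features(cohort, predictor)
  y <- build_targets(cohort$outcomes, measure, timepoint)
  ids <- intersect(rownames(X), names(y))
  list(X = X[ids, , drop = FALSE], y = y[ids])
}

# The four proportional-change target columns of the factorial grid,
# aligned to the baseline feature rows.
target_matrix <- function(cohort) {
  X <- cohort_features(cohort, "baseline_fc")
  combos <- list(c("functioning", 6), c("functioning", 12),
                 c("symptoms", 6), c("symptoms", 12))
  Y <- sapply(combos, function(ct)
    build_targets(cohort$outcomes, ct[[1]], as.numeric(ct[[2]]))[rownames(X)])
  colnames(Y) <- c("fun6", "fun12", "sym6", "sym12")
  list(X = X, Y = Y)
}
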