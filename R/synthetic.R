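# Synthetic longitudinal FC cohorts with known ground truth: a shared
# low-rank network backbone plus subject-level perturbations generates
# the time series; a sparse planted edge-weight vector couples realised
# FC to outcome change at a controllable effect size; attrition is
# missing-completely-at-random; clinical scales are bounded.

#' Configuration for a synthetic longitudinal FC cohort
#'
#' Collects and validates every knob of the generator. Defaults emulate
#' the study conditions of a mid-2010s first-episode-psychosis trial
#' cohort: 55 antipsychotic-naive patients, a 419-region parcellation,
#' roughly a third of subjects lacking the 3-month scan, outcomes on a
#' 0-100 functioning scale (SOFAS-like) and a 24-item symptom scale
#' (BPRS-like, items 1-7), and -- reflecting that study's null result --
#' no planted FC-outcome coupling unless `effect_r2 > 0` is requested.
#'
#' @param n_subjects Number of subjects (default 55).
#' @param n_regions Parcellation size (default 419).
#' @param n_timepoints BOLD-like samples per scan (default 150, >= 3).
#' @param effect_r2 Fraction of outcome-change variance explained by the
#'   planted FC signal, in `[0, 1]` (default 0).
#' @param n_causal_edges Number of edges with nonzero planted weight
#'   (default 5; must be positive whenever `effect_r2 > 0`).
#' @param attrition_fraction Fraction of subjects lacking the 3-month
#'   scan, in `[0, 1]` (default 0.35).
#' @param scale_cor Correlation between the noise components of the two
#'   outcome scales (default 0.3; symptoms and functioning are related
#'   but not interchangeable).
#' @param arm_fraction Fraction of subjects labelled `"placebo"`
#'   (default 0.5, a 1:1 randomisation).
#' @param change_sd Between-subject SD of the proportional-change
#'   targets (default 0.25).
#' @param n_latent Rank of the shared network backbone (default 5).
#' @param subject_sd Scale of subject-level loading perturbations
#'   (default 0.35); drives realistic between-subject FC variance.
#' @param drift_sd Scale of the 3-month loading drift (default 0.15);
#'   makes delta-FC matrices non-trivial.
#' @param seed Integer seed; the cohort is a pure function of the
#'   config including this seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 55L, n_regions = 419L,
                          n_timepoints = 150L, effect_r2 = 0,
                          n_causal_edges = 5L, attrition_fraction = 0.35,
                          scale_cor = 0.3, arm_fraction = 0.5,
                          change_sd = 0.25, n_latent = 5L,
                          subject_sd = 0.35, drift_sd = 0.15, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions),
              n_timepoints = as.integer(n_timepoints),
              effect_r2 = effect_r2, n_causal_edges = as.integer(n_causal_edges),
              attrition_fraction = attrition_fraction, scale_cor = scale_cor,
              arm_fraction = arm_fraction, change_sd = change_sd,
              n_latent = as.integer(n_latent), subject_sd = subject_sd,
              drift_sd = drift_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1) stop("n_subjects must be positive")
    if (n_regions < 2) stop("n_regions must be at least 2")
    if (n_timepoints < 3) stop("n_timepoints must be at least 3")
    if (effect_r2 < 0 || effect_r2 > 1) stop("effect_r2 must lie in [0, 1]")
    if (attrition_fraction < 0 || attrition_fraction > 1)
      stop("attrition_fraction must lie in [0, 1]")
    if (arm_fraction < 0 || arm_fraction > 1)
      stop("arm_fraction must lie in [0, 1]")
    if (abs(scale_cor) > 1) stop("scale_cor must lie in [-1, 1]")
    if (n_causal_edges < 0 || n_causal_edges > n_regions * (n_regions - 1) / 2)
      stop("n_causal_edges must lie in [0, n_regions*(n_regions-1)/2]")
    if (effect_r2 > 0 && n_causal_edges == 0)
      stop("effect_r2 > 0 requires at least one causal edge")
  })
  structure(cfg, class = "cohort_config")
}

# Redistribute overflow above `cap` proportionally to remaining
# headroom; preserves the vector sum. Feasible whenever
# sum(x) <= cap * length(x) and x >= 0.
redistribute_cap <- function(x, cap) {
  for (it in 1:50) {
    over <- x > cap
    if (!any(over)) break
    excess <- sum(x[over] - cap)
    x[over] <- cap
    head_room <- cap - x
    free <- head_room > 0
    if (!any(free)) break
    x[free] <- x[free] + excess * head_room[free] / sum(head_room[free])
  }
  pmin(x, cap)
}

# One scan's parcellated time series: low-rank loadings D (regions x
# n_latent) drive correlated activity, plus white region noise.
simulate_scan <- function(D, n_timepoints, noise_sd = 1) {
  Z <- matrix(stats::rnorm(ncol(D) * n_timepoints), ncol(D), n_timepoints)
  D %*% Z + noise_sd * matrix(stats::rnorm(nrow(D) * n_timepoints),
                              nrow(D), n_timepoints)
}

#' Generate a synthetic longitudinal FC cohort
#'
#' Simulates, per subject: a baseline parcellated time series (and a
#' 3-month series unless the subject is hit by attrition), a treatment
#' arm label, and outcome scores at baseline, 6 and 12 months on the
#' two clinical scales. A sparse edge-weight vector `w` (signs +/-1 on
#' `n_causal_edges` random edges) defines a latent signal
#' `g = w . FCVector(subject)` from the realised baseline FC; the
#' proportional-change outcome targets are built as
#' `mu + change_sd * (sqrt(effect_r2) * z(g) + sqrt(1 - effect_r2) * e)`
#' with independent standard-normal noise `e` (correlated `scale_cor`
#' across the two scales), then anchored to baseline scores so that
#' `(y2 - y1)/y1` reproduces the planted target exactly. Targets are
#' clamped where needed to keep follow-up scores inside scale bounds,
#' and the clamped value is what is stored as ground truth. Attrition
#' removes the 3-month scan of a missing-completely-at-random subset.
#'
#' @param config A [cohort_config()].
#' @return An object of class `fc_cohort`: list with `config`,
#'   `subjects` (per-subject `ts_baseline`, `ts_followup` or `NULL`,
#'   `arm`), `outcomes` (long-format table), `bprs_items` (item-level
#'   table), and `truth` (`w`, `causal_edges`, `signal`, `targets`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 8, n_regions = 6,
#'                                      n_timepoints = 40, seed = 3))
#' nrow(coh$outcomes)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    p <- cfg$n_regions
    labels <- sprintf("R%03d", seq_len(p))
    ids <- sprintf("sub-%03d", seq_len(n))
    n_edges <- p * (p - 1) / 2

    # shared backbone + per-subject perturbation
    L <- matrix(stats::rnorm(p * cfg$n_latent), p, cfg$n_latent)
    subjects <- vector("list", n)
    fcv <- matrix(NA_real_, n, n_edges)
    n_missing <- round(cfg$attrition_fraction * n)
    missing_scan <- sort(sample.int(n, n_missing))
    n_placebo <- round(cfg$arm_fraction * n)
    placebo <- sort(sample.int(n, n_placebo))

    for (s in seq_len(n)) {
      D <- L + cfg$subject_sd * matrix(stats::rnorm(p * cfg$n_latent),
                                       p, cfg$n_latent)
      ts1 <- simulate_scan(D, cfg$n_timepoints)
      rownames(ts1) <- labels
      colnames(ts1) <- seq_len(cfg$n_timepoints)
      ts2 <- NULL
      if (!(s %in% missing_scan)) {
        D2 <- D + cfg$drift_sd * matrix(stats::rnorm(p * cfg$n_latent),
                                        p, cfg$n_latent)
        ts2 <- simulate_scan(D2, cfg$n_timepoints)
        rownames(ts2) <- labels
        colnames(ts2) <- seq_len(cfg$n_timepoints)
      }
      fcv[s, ] <- fc_vectorize(compute_fc(ts1))
      subjects[[s]] <- list(id = ids[s], ts_baseline = ts1, ts_followup = ts2,
                            arm = if (s %in% placebo) "placebo" else "medication")
    }

    # planted sparse weights and latent signal
    w <- rep(0, n_edges)
    causal <- integer(0)
    if (cfg$n_causal_edges > 0) {
      causal <- sort(sample.int(n_edges, cfg$n_causal_edges))
      # a sign-coherent circuit: stronger coupling across these edges
      # tracks better outcomes, the configuration CPM's signed
      # selection is designed to detect
      w[causal] <- 1
    }
    g <- drop(fcv %*% w)
    z <- if (length(causal) && stats::sd(g) > 0) (g - mean(g)) / stats::sd(g)
         else rep(0, n)

    # outcome construction: baseline anchors with realistic moments,
    # follow-ups derived multiplicatively from the planted targets
    bounds <- list(SOFAS = c(0, 100), BPRS = c(24, 168))
    base_mean <- c(SOFAS = 52.5, BPRS = 57.8)
    base_sd <- c(SOFAS = 12.4, BPRS = 9.4)
    mu_change <- list(SOFAS = c(`6` = 0.20, `12` = 0.22),
                      BPRS = c(`6` = -0.25, `12` = -0.23))
    rho <- cfg$scale_cor

    y1 <- list()
    for (sc in c("SOFAS", "BPRS")) {
      lo <- bounds[[sc]][1] + 0.1 * diff(bounds[[sc]])
      hi <- bounds[[sc]][2] - 0.1 * diff(bounds[[sc]])
      y1[[sc]] <- pmin(pmax(stats::rnorm(n, base_mean[sc], base_sd[sc]), lo), hi)
    }

    targets <- NULL
    scores <- list(SOFAS = list(`0` = y1$SOFAS), BPRS = list(`0` = y1$BPRS))
    sig_amp <- sqrt(cfg$effect_r2)
    noise_amp <- sqrt(1 - cfg$effect_r2)
    for (tp in c(6, 12)) {
      e1 <- stats::rnorm(n)
      e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
      noise <- list(SOFAS = e1, BPRS = e2)
      for (sc in c("SOFAS", "BPRS")) {
        ch <- mu_change[[sc]][as.character(tp)] +
          cfg$change_sd * (sig_amp * z + noise_amp * noise[[sc]])
        y2 <- pmin(pmax(y1[[sc]] * (1 + ch), bounds[[sc]][1]), bounds[[sc]][2])
        ch <- y2 / y1[[sc]] - 1   # clamped target is the stored ground truth
        scores[[sc]][[as.character(tp)]] <- y2
        targets <- rbind(targets,
                         data.frame(subject_id = ids,
                                    scale = sc, visit_month = tp,
                                    change = ch))
      }
    }

    outcomes <- do.call(rbind, lapply(c("SOFAS", "BPRS"), function(sc) {
      do.call(rbind, lapply(c(0, 6, 12), function(tp) {
        data.frame(subject_id = ids,
                   arm = vapply(subjects, `[[`, "", "arm"),
                   scale = sc, visit_month = tp,
                   score = scores[[sc]][[as.character(tp)]])
      }))
    }))
    rownames(outcomes) <- NULL

    # BPRS item-level scores: baseline item excesses proportional to a
    # per-subject random profile, follow-up excesses rescaled so item
    # sums track the total score; items capped into [1, 7]
    n_items <- length(bprs_item_names)
    items <- vector("list", n)
    for (s in seq_len(n)) {
      u <- stats::runif(n_items, 0.5, 1.5)
      e0 <- redistribute_cap((scores$BPRS$`0`[s] - 24) * u / sum(u), 6)
      rows <- data.frame(subject_id = ids[s], visit_month = 0,
                         item = bprs_item_names, score = 1 + e0)
      for (tp in c(6, 12)) {
        tot <- scores$BPRS[[as.character(tp)]][s]
        f <- (tot - 24) / max(sum(e0), 1e-12)
        e2 <- redistribute_cap(e0 * f, 6)
        rows <- rbind(rows, data.frame(subject_id = ids[s], visit_month = tp,
                                       item = bprs_item_names, score = 1 + e2))
      }
      items[[s]] <- rows
    }
    bprs_items <- do.call(rbind, items)
    rownames(bprs_items) <- NULL

    structure(list(config = cfg, subjects = subjects, outcomes = outcomes,
                   bprs_items = bprs_items,
                   truth = list(w = w, causal_edges = causal, signal = g,
                                targets = targets,
                                edge_index = edge_index(p)),
                   baseline_fcv = fcv),
              class = "fc_cohort")
  })
}

#' @export
print.fc_cohort <- function(x, ...) {
  n2 <- sum(!vapply(x$subjects, function(s) is.null(s$ts_followup), logical(1)))
  cat(sprintf("<fc_cohort> %d subjects (%d with 3-month scan), %d regions, effect_r2 = %g\n",
              x$config$n_subjects, n2, x$config$n_regions, x$config$effect_r2))
  invisible(x)
}

#' Extract the feature matrix for one predictor type
#'
#' Returns the subjects-by-edges matrix of vectorised FC features for
#' either the baseline FC or the 3-month FC change, restricted to the
#' subjects for whom that predictor exists (delta features require both
#' scans; no imputation).
#'
#' @param cohort An `fc_cohort`.
#' @param predictor `"baseline_fc"` or `"delta_fc"`.
#' @return Numeric matrix with subject IDs as rownames.
#' @export
cohort_features <- function(cohort, predictor = c("baseline_fc", "delta_fc")) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(cohort, "fc_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    if (predictor == "baseline_fc") {
      fc_vectorize(compute_fc(s$ts_baseline))
    } else {
      if (is.null(s$ts_followup)) return(NULL)
      b <- compute_fc(s$ts_baseline)
      f <- compute_fc(s$ts_followup, kind = "followup_fc")
      fc_vectorize(delta_fc(b, f))
    }
  })
  keep <- !vapply(rows, is.null, logical(1))
  X <- do.call(rbind, rows[keep])
  rownames(X) <- vapply(cohort$subjects[keep], `[[`, "", "id")
  X
}

#' Export a cohort to delimited text files
#'
#' Writes one tab-delimited time-series file per scan (regions in rows,
#' samples in columns, header row of sample indices, first column
#' region labels), the long-format outcome table `outcomes.csv`, the
#' item-level table `bprs_items.csv`, and the planted ground truth
#' `ground_truth_edges.csv` (columns i, j, weight). Round-trips
#' losslessly through [load_cohort()].
#'
#' @param cohort An `fc_cohort`.
#' @param directory Output directory.
#' @param force Overwrite an existing directory? Default `FALSE`.
#' @return `directory`, invisibly.
#' @export
export_cohort <- function(cohort, directory, force = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (dir.exists(directory)) {
    if (!force) stop("directory exists; use force = TRUE to overwrite")
    unlink(directory, recursive = TRUE)
  }
  dir.create(directory, recursive = TRUE)
  # %.17g round-trips IEEE doubles exactly through text
  fmt <- function(x) sprintf("%.17g", x)
  write_ts <- function(ts, path) {
    df <- data.frame(region = rownames(ts),
                     apply(ts, 2, fmt), check.names = FALSE)
    colnames(df) <- c("region", colnames(ts))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (s in cohort$subjects) {
    write_ts(s$ts_baseline, file.path(directory, paste0(s$id, "_baseline.tsv")))
    if (!is.null(s$ts_followup))
      write_ts(s$ts_followup, file.path(directory, paste0(s$id, "_month3.tsv")))
  }
  out_tab <- cohort$outcomes
  out_tab$score <- fmt(out_tab$score)
  utils::write.csv(out_tab, file.path(directory, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  item_tab <- cohort$bprs_items
  item_tab$score <- fmt(item_tab$score)
  utils::write.csv(item_tab, file.path(directory, "bprs_items.csv"),
                   row.names = FALSE, quote = FALSE)
  ce <- cohort$truth$causal_edges
  gt <- data.frame(i = cohort$truth$edge_index[ce, "i"],
                   j = cohort$truth$edge_index[ce, "j"],
                   weight = cohort$truth$w[ce])
  utils::write.csv(gt, file.path(directory, "ground_truth_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(directory)
}

#' Rebuild a study-ready cohort object from exported files
#'
#' Reads a directory written by [export_cohort()] (or any directory
#' following the same layout) and assembles an `fc_cohort` suitable
#' for [run_study()]. Ground truth is not reconstructed: real cohorts
#' have none.
#'
#' @param directory Directory of per-subject time-series TSVs and the
#'   outcome tables.
#' @return An `fc_cohort` with `truth = NULL`.
#' @export
cohort_from_files <- function(directory) {
  raw <- load_cohort(directory)
  ids <- names(raw$timeseries)
  arms <- vapply(ids, function(id) {
    a <- unique(raw$outcomes$arm[raw$outcomes$subject_id == id])
    if (length(a)) as.character(a[1]) else "medication"
  }, character(1))
  subjects <- lapply(seq_along(ids), function(i) {
    ts <- raw$timeseries[[i]]
    list(id = ids[i], ts_baseline = ts$baseline,
         ts_followup = ts$month3, arm = arms[i])
  })
  n_regions <- nrow(subjects[[1]]$ts_baseline)
  cfg <- cohort_config(n_subjects = length(ids), n_regions = n_regions,
                       n_timepoints = ncol(subjects[[1]]$ts_baseline),
                       attrition_fraction = 0)
  structure(list(config = cfg, subjects = subjects,
                 outcomes = raw$outcomes, bprs_items = raw$bprs_items,
                 truth = NULL),
            class = "fc_cohort")
}

#' Load an exported cohort directory
#'
#' Reads the files written by [export_cohort()] back into memory.
#'
#' @param directory Directory written by [export_cohort()].
#' @return List with `timeseries` (per subject: `baseline` and
#'   optionally `month3` region-by-sample matrices), `outcomes`, and
#'   `bprs_items`.
#' @export
load_cohort <- function(directory) {
  read_ts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  files <- list.files(directory, pattern = "_baseline\\.tsv$")
  ids <- sub("_baseline\\.tsv$", "", files)
  timeseries <- lapply(ids, function(id) {
    out <- list(baseline = read_ts(file.path(directory, paste0(id, "_baseline.tsv"))))
    f2 <- file.path(directory, paste0(id, "_month3.tsv"))
    if (file.exists(f2)) out$month3 <- read_ts(f2)
    out
  })
  names(timeseries) <- ids
  outcomes <- utils::read.csv(file.path(directory, "outcomes.csv"))
  items_path <- file.path(directory, "bprs_items.csv")
  bprs_items <- if (file.exists(items_path)) utils::read.csv(items_path) else NULL
  list(timeseries = timeseries, outcomes = outcomes, bprs_items = bprs_items)
}
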