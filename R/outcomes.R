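# Clinical outcome targets: proportional change scores, per-subject
# slopes over the follow-up year, and the positive-symptom subscale.

#' Names of the 24 BPRS items
#'
#' Item labels for the 24-item Brief Psychiatric Rating Scale (each item
#' scored 1-7). Four items index positive psychotic symptoms and are
#' summed by [positive_symptom_score()].
#'
#' @format Character vector of length 24.
#' @export
bprs_item_names <- c(
  "somatic_concern", "anxiety", "depression", "suicidality",
  "guilt", "hostility", "elevated_mood", "grandiosity",
  "suspiciousness", "hallucinations", "unusual_thought_content",
  "bizarre_behavior", "self_neglect", "disorientation",
  "conceptual_disorganization", "blunted_affect",
  "emotional_withdrawal", "motor_retardation", "tension",
  "uncooperativeness", "excitement", "distractibility",
  "motor_hyperactivity", "mannerisms_posturing"
)

#' The four BPRS items indexing positive symptoms
#' @format Character vector of length 4.
#' @export
bprs_positive_items <- c(
  "unusual_thought_content", "conceptual_disorganization",
  "hallucinations", "grandiosity"
)

#' Proportional change score between two visits
#'
#' The continuous outcome target: `(y2 - y1) / y1`, the change in a
#' clinical scale between baseline and a later visit expressed as a
#' fraction of the baseline score. Undefined (an error) at `y1 = 0`.
#' Scale-invariant: rescaling both scores by any positive constant
#' leaves the value unchanged.
#'
#' @param y1 Baseline score (nonzero).
#' @param y2 Follow-up score.
#' @return `(y2 - y1) / y1`, vectorised.
#' @examples
#' proportional_change(50, 60)  # 0.20
#' @export
proportional_change <- function(y1, y2) {
  if (any(y1 == 0)) stop("proportional change undefined at baseline score 0")
  (y2 - y1) / y1
}

#' Per-subject outcome slope over the follow-up period
#'
#' Ordinary least-squares slope of scale score on visit time (months),
#' fitted to whichever visits a subject has (2 or 3 points); an
#' alternative outcome definition that is robust to the exact timing of
#' single assessments.
#'
#' @param visit_months Numeric vector of visit times in months.
#' @param scores Numeric vector of scores at those visits (`NA` allowed;
#'   such visits are dropped).
#' @return Slope in score units per month.
#' @examples
#' slope_outcome(c(0, 6, 12), c(50, 60, 70))  # 5/3 per month
#' @export
slope_outcome <- function(visit_months, scores) {
  keep <- !is.na(scores) & !is.na(visit_months)
  t <- visit_months[keep]
  y <- scores[keep]
  if (length(t) < 2 || length(unique(t)) < 2)
    stop("slope requires at least 2 distinct visit times with scores")
  stats::cov(t, y) / stats::var(t)
}

#' Positive-symptom subscale score
#'
#' Sum of the four BPRS items indexing positive psychotic symptoms:
#' unusual thought content, conceptual disorganization, hallucinatory
#' behavior, and grandiosity. Range 4-28.
#'
#' @param item_scores Named numeric vector of BPRS item scores (names
#'   from [bprs_item_names]); all four positive items must be present.
#' @return Sum of the four positive-symptom items.
#' @examples
#' x <- setNames(rep(1, 24), bprs_item_names)
#' positive_symptom_score(x)  # 4
#' @export
positive_symptom_score <- function(item_scores) {
  missing_items <- setdiff(bprs_positive_items, names(item_scores))
  if (length(missing_items) > 0)
    stop("missing BPRS item(s): ", paste(missing_items, collapse = ", "))
  vals <- item_scores[bprs_positive_items]
  if (anyNA(vals))
    stop("missing BPRS item(s): ",
         paste(bprs_positive_items[is.na(vals)], collapse = ", "))
  sum(vals)
}

# Validate the long-format outcome table (subject_id, arm, scale,
# visit_month, score).
check_outcome_table <- function(table) {
  needed <- c("subject_id", "scale", "visit_month", "score")
  if (!all(needed %in% names(table)))
    stop("outcome table must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(table[, c("subject_id", "scale", "visit_month")]))
    stop("at most one score per (subject, scale, visit)")
  sofas <- table$score[table$scale == "SOFAS" & !is.na(table$score)]
  if (length(sofas) && (min(sofas) < 0 || max(sofas) > 100))
    stop("SOFAS scores must lie in [0, 100]")
  bprs <- table$score[table$scale == "BPRS" & !is.na(table$score)]
  if (length(bprs) && (min(bprs) < 24 || max(bprs) > 168))
    stop("BPRS total scores must lie in [24, 168]")
  invisible(table)
}

#' Build per-subject prediction targets from an outcome table
#'
#' Turns raw longitudinal scale scores into one numeric target per
#' subject, for one cell of the factorial model grid: an outcome
#' measure (functioning = SOFAS, symptoms = BPRS), a time point (6- or
#' 12-month change), and a target definition. Subjects missing a
#' required score are dropped, never imputed.
#'
#' Target definitions:
#' \describe{
#'   \item{proportional_change}{`(y2 - y1) / y1` between baseline and the
#'     requested visit.}
#'   \item{slope}{OLS slope of score on visit month over all available
#'     visits (the `timepoint` argument is ignored).}
#'   \item{positive_change}{proportional change of the 4-item
#'     positive-symptom sum (symptoms only; requires `items`).}
#' }
#'
#' @param table Long-format outcome table with columns `subject_id`,
#'   `arm`, `scale`, `visit_month`, `score`.
#' @param measure `"functioning"` (SOFAS) or `"symptoms"` (BPRS).
#' @param timepoint Follow-up visit in months, 6 or 12.
#' @param outcome_kind One of `"proportional_change"`, `"slope"`,
#'   `"positive_change"`.
#' @param items Item-level BPRS table (columns `subject_id`,
#'   `visit_month`, `item`, `score`), required for `"positive_change"`.
#' @param arm Optional treatment-arm filter (`"placebo"` or
#'   `"medication"`) applied before target construction.
#' @return Named numeric vector (names = subject IDs) with attributes
#'   `n_total` (subjects considered) and `dropped` (IDs excluded for
#'   missing scores).
#' @examples
#' tab <- data.frame(subject_id = "s1", arm = "placebo", scale = "SOFAS",
#'                   visit_month = c(0, 6), score = c(50, 60))
#' build_targets(tab, "functioning", 6)  # s1 -> 0.2
#' @export
build_targets <- function(table, measure = c("functioning", "symptoms"),
                          timepoint = 6,
                          outcome_kind = c("proportional_change", "slope",
                                           "positive_change"),
                          items = NULL, arm = NULL) {
  measure <- match.arg(measure)
  outcome_kind <- match.arg(outcome_kind)
  if (!timepoint %in% c(6, 12)) stop("timepoint must be 6 or 12")
  check_outcome_table(table)
  if (!is.null(arm)) {
    arm <- match.arg(arm, c("placebo", "medication"))
    table <- table[table$arm == arm, , drop = FALSE]
  }
  scale_name <- if (measure == "functioning") "SOFAS" else "BPRS"
  tab <- table[table$scale == scale_name, , drop = FALSE]
  subjects <- unique(tab$subject_id)
  n_total <- length(subjects)

  if (outcome_kind == "positive_change") {
    if (measure != "symptoms")
      stop("positive-symptom targets are defined for the symptoms measure only")
    if (is.null(items)) stop("positive_change requires the item-level table")
    if (!is.null(arm)) items <- items[items$subject_id %in% subjects, , drop = FALSE]
    subjects <- unique(items$subject_id)
    n_total <- length(subjects)
  }

  target_one <- function(sid) {
    if (outcome_kind == "slope") {
      rows <- tab[tab$subject_id == sid & !is.na(tab$score), , drop = FALSE]
      if (nrow(rows) < 2 || length(unique(rows$visit_month)) < 2) return(NA_real_)
      return(slope_outcome(rows$visit_month, rows$score))
    }
    if (outcome_kind == "positive_change") {
      sub <- items[items$subject_id == sid, , drop = FALSE]
      score_at <- function(m) {
        v <- sub[sub$visit_month == m, , drop = FALSE]
        sc <- stats::setNames(v$score, v$item)
        if (!all(bprs_positive_items %in% names(sc))) return(NA_real_)
        positive_symptom_score(sc)
      }
      y1 <- score_at(0); y2 <- score_at(timepoint)
      if (is.na(y1) || is.na(y2) || y1 == 0) return(NA_real_)
      return(proportional_change(y1, y2))
    }
    rows <- tab[tab$subject_id == sid, , drop = FALSE]
    y1 <- rows$score[rows$visit_month == 0]
    y2 <- rows$score[rows$visit_month == timepoint]
    if (length(y1) != 1 || length(y2) != 1 || is.na(y1) || is.na(y2) || y1 == 0)
      return(NA_real_)
    proportional_change(y1, y2)
  }

  out <- vapply(subjects, target_one, numeric(1))
  names(out) <- subjects
  dropped <- subjects[is.na(out)]
  out <- out[!is.na(out)]
  if (length(out) == 0) stop("no subjects with complete scores for this target")
  attr(out, "n_total") <- n_total
  attr(out, "dropped") <- dropped
  out
}
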