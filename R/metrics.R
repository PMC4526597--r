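#' Devaluation sensitivity of one subject
#'
#' Exp 1: number of test-phase responses in the valued game minus the
#' number in the devalued game (each 0..10, score -10..10; 10 is maximal
#' devaluation sensitivity, 0 equal responding in both states). Exp 2:
#' proportion of test choices directed at the still-valued outcome.
#'
#' @param trials trial records of a single subject.
#' @param config a [task_config()].
#' @return Integer score (Exp 1) or proportion (Exp 2).
#' @export
devaluation_sensitivity <- function(trials, config) {
  test <- trials[trials$phase == "test", ]
  if (nrow(test) == 0) stop("no test-phase trials found", call. = FALSE)
  if (length(unique(test$subject)) > 1)
    stop("devaluation_sensitivity expects a single subject", call. = FALSE)
  if (config$experiment == "exp1") {
    responded <- test$action != "none"
    sum(responded & !test$devalued_game) - sum(responded & test$devalued_game)
  } else {
    chosen <- test[test$action != "none", ]
    if (nrow(chosen) == 0) stop("no test-phase choices found", call. = FALSE)
    mean(!chosen$devalued_game)
  }
}

#' Consumption sensitivity
#'
#' Valued coins collected minus devalued coins collected in the
#' consumption display (10 of each available); 10 indicates a maximal
#' shift in incentive value toward valued coins, 0 no differentiation.
#'
#' @param valued,devalued collected-coin counts, each in 0..10.
#' @return Integer score in -10..10 (vectorized).
#' @export
consumption_sensitivity <- function(valued, devalued) {
  if (any(valued < 0 | valued > 10 | devalued < 0 | devalued > 10))
    stop("collected-coin counts must be in 0..10", call. = FALSE)
  as.integer(valued - devalued)
}

#' z-score a vector
#'
#' Centers to mean 0 and scales to SD 1 (denominator n - 1).
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least two values to z-score",
                               call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant vector (zero variance)", call. = FALSE)
  (values - mean(values)) / s
}

#' Subject-level summaries of a cohort
#'
#' One row per subject: devaluation sensitivity, consumption sensitivity,
#' missed-trial count and fraction (training phase), and the fraction of
#' training responses made with the most-used key.
#'
#' @param cohort a [generate_cohort()] object.
#' @return Data frame of class `subject_summary`.
#' @export
subject_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  trials <- cohort$trials
  config <- cohort$config
  subjects <- sort(unique(trials$subject))
  rows <- lapply(subjects, function(s) {
    tr <- trials[trials$subject == s, ]
    train <- tr[tr$phase == "training", ]
    resp <- train$action[train$action != "none"]
    same_key <- if (length(resp)) max(table(resp)) / length(resp) else NA_real_
    data.frame(
      subject = s,
      deval_sensitivity = devaluation_sensitivity(tr, config),
      n_missed = sum(train$action == "none"),
      missed_fraction = mean(train$action == "none"),
      same_key_fraction = same_key
    )
  })
  out <- do.call(rbind, rows)
  cons <- cohort$consumption
  out$consumption_sensitivity <-
    consumption_sensitivity(cons$valued, cons$devalued)[
      match(out$subject, cons$subject)]
  class(out) <- c("subject_summary", "data.frame")
  out
}

#' Quality-control exclusion filters
#'
#' Excludes subjects who missed more than 10 % of training trials,
#' responded with the same key on more than 90 % of responses, or (when a
#' reaction-time summary is supplied) whose mean reaction time lies beyond
#' 2 SDs of the cohort mean. Thresholds are strict inequalities. The
#' filters are idempotent: reapplying them to the retained set removes
#' nobody (RT bounds are frozen from the first application's cohort).
#'
#' @param summaries a [subject_summaries()] data frame.
#' @param rt_summary optional data frame with columns `subject`, `mean_rt`.
#' @param rt_bounds optional precomputed RT bounds (used on reapplication).
#' @return List with `retained` (summaries of retained subjects) and
#'   `report` (subject, excluded, reason) plus the RT bounds used.
#' @export
apply_exclusions <- function(summaries, rt_summary = NULL, rt_bounds = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  reason <- rep(NA_character_, nrow(summaries))
  reason[summaries$missed_fraction > 0.10] <- "missed"
  sk <- !is.na(summaries$same_key_fraction) & summaries$same_key_fraction > 0.90
  reason[is.na(reason) & sk] <- "same_key"
  if (!is.null(rt_summary)) {
    mrt <- rt_summary$mean_rt[match(summaries$subject, rt_summary$subject)]
    if (is.null(rt_bounds)) {
      m <- mean(mrt, na.rm = TRUE); s <- stats::sd(mrt, na.rm = TRUE)
      rt_bounds <- c(m - 2 * s, m + 2 * s)
    }
    rt_bad <- !is.na(mrt) & (mrt < rt_bounds[1] | mrt > rt_bounds[2])
    reason[is.na(reason) & rt_bad] <- "rt"
  }
  excluded <- !is.na(reason)
  if (all(excluded))
    stop("all subjects excluded; no cohort remains", call. = FALSE)
  list(retained = summaries[!excluded, , drop = FALSE],
       report = data.frame(subject = summaries$subject, excluded = excluded,
                           reason = reason, stringsAsFactors = FALSE),
       rt_bounds = rt_bounds)
}

#' Paired comparison of valued vs devalued coin consumption
#'
#' Manipulation check that the simulated devaluation shifted collection
#' toward valued coins: paired mean difference with a paired t statistic
#' (equivalent to the one-way repeated-measures F on two levels).
#'
#' @param consumption data frame with columns `valued`, `devalued` (counts
#'   per subject).
#' @return List with `mean_valued`, `mean_devalued`, `mean_diff`,
#'   `statistic` (paired t), `df`, and `p_value`.
#' @export
paired_value_comparison <- function(consumption) {
  stopifnot(all(c("valued", "devalued") %in% names(consumption)))
  n <- nrow(consumption)
  if (n < 3) stop("need at least 3 subjects for the paired comparison",
                  call. = FALSE)
  d <- consumption$valued - consumption$devalued
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf),
               parameter = c(df = n - 1),
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(consumption$valued, consumption$devalued,
                        paired = TRUE)
  }
  list(mean_valued = mean(consumption$valued),
       mean_devalued = mean(consumption$devalued),
       mean_diff = mean(d),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Spearman rank correlation with average ranks for ties
#'
#' @param x,y numeric vectors.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
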