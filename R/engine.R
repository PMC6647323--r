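# Orchestration of one trial replicate on the calendar: enrollment via a
# recruitment strategy, event accrual, interim trigger and decision, stage-2
# conduct, final-analysis trigger, stage-wise testing.
#
# Follow-up F is a calibration horizon for the survival model, not a
# per-patient censoring time: in the adaptive designs patients are followed
# until the relevant data cut, and the final analysis is event-driven (270
# events overall on the continue-O path; the prevalence-scaled positive
# event target after enrichment). The non-enriched comparator is a
# fixed-horizon design: its final analysis is at calendar time R + F, with
# one interim futility look at the interim event count and no decision lag.

#' Stage data at a calendar cut
#'
#' Extracts the survival records known at calendar time `cut_time` for one
#' population slice: time on study (administratively censored at the cut
#' and at any enrichment censoring time) and event indicator.
#'
#' @param log an `enrollment_log`
#' @param cut_time calendar data-cut time
#' @param population `"O"` (everyone) or `"P"` (biomarker-positives)
#' @param cohort optional cohort filter (`"stage1"` or `"stage2"`)
#' @return data.frame with `time`, `event`, `arm`, `biomarker`
#' @export
stage_data <- function(log, cut_time, population = c("O", "P"), cohort = NULL) {
  population <- match.arg(population)
  keep <- log$enrolled & log$enrollment_time < cut_time
  if (population == "P") keep <- keep & log$biomarker == "positive"
  if (!is.null(cohort)) keep <- keep & log$cohort == cohort
  sl <- log[keep, , drop = FALSE]
  end <- pmin(sl$enrollment_time + sl$latent_event_time, sl$censoring_time, cut_time)
  data.frame(time = end - sl$enrollment_time,
             event = as.integer(sl$enrollment_time + sl$latent_event_time <=
                                  pmin(sl$censoring_time, cut_time)),
             arm = sl$arm, biomarker = sl$biomarker,
             stringsAsFactors = FALSE)
}

#' Calendar time of the interim trigger
#'
#' Earliest calendar time at which `target_events` events have occurred
#' among the enrolled patients of the given cohort (event calendar time =
#' enrollment time + latent event time).
#'
#' @param log an `enrollment_log`
#' @param target_events event count triggering the interim look (>= 1)
#' @param cohort cohort whose events count toward the trigger (default
#'   stage 1); `NULL` counts all enrolled patients
#' @return calendar time of the `target_events`-th event
#' @export
interim_trigger_time <- function(log, target_events, cohort = "stage1") {
  if (!is.numeric(target_events) || target_events < 1)
    stop_invalid("`target_events` must be >= 1")
  keep <- log$enrolled
  if (!is.null(cohort)) keep <- keep & log$cohort == cohort
  ev <- sort(log$enrollment_time[keep] + log$latent_event_time[keep])
  if (length(ev) < target_events)
    stop_invalid("cohort can never accumulate the targeted interim events")
  ev[target_events]
}

#' Calendar time of the final-analysis trigger
#'
#' Continue-O path: earliest time at which `total_events` events have
#' occurred among all enrolled patients. Enrichment path: earliest time at
#' which `round(total_events * prevalence)` events have occurred among
#' enrolled biomarker-positives (events of censored negatives do not
#' count). Futility path: the decision time. If the remaining patients can
#' never reach the target, the cut falls at the last reachable event with a
#' warning.
#'
#' @param log an `enrollment_log`
#' @param decision realized interim decision
#' @param design a [trial_design()]
#' @param decision_time calendar time the decision was enacted
#' @return calendar time of the final data cut
#' @export
final_trigger_time <- function(log, decision, design, decision_time) {
  if (decision == "futility") return(decision_time)
  if (decision == "continue_O") {
    keep <- log$enrolled
    target <- design$total_events
  } else {
    keep <- log$enrolled & log$biomarker == "positive"
    target <- round_half_up(design$total_events * design$prevalence)
  }
  evt <- log$enrollment_time[keep] + log$latent_event_time[keep]
  evt <- sort(evt[evt <= log$censoring_time[keep]])
  if (length(evt) < target) {
    warning(sprintf("final event target %d unreachable (%d attainable); cutting at the last event",
                    as.integer(target), length(evt)), call. = FALSE)
    return(evt[length(evt)])
  }
  evt[target]
}

# Capped hazard-ratio estimate that never errors: degenerate interim data
# (no events in one arm) fall on the "not beneficial" side via the cap.
safe_hazard_ratio <- function(data, cap = 1e3) {
  suppressWarnings(tryCatch(estimate_hazard_ratio(data, cap = cap),
                            error = function(e) cap))
}

#' Run one trial replicate
#'
#' Executes a full replicate on the calendar for one recruitment strategy:
#' stage-1 enrollment, interim trigger and hazard-ratio decision, strategy
#' application (with enrichment censoring of negatives where applicable),
#' final-analysis trigger, stage-wise one-sided log-rank p-values, and the
#' closed-testing decision. The comparator (`"non_enriched"`) instead runs
#' a single-phase trial with a futility-only interim look at the interim
#' event count and a final log-rank test of the overall population at the
#' fixed horizon R + F.
#'
#' @param design a [trial_design()]
#' @param stream a `patient_stream` of size `design$tss`
#' @param strategy recruitment strategy name
#' @param keep_data if TRUE, attach the enrollment log and stage data used
#'   for testing (for diagnostics)
#' @return a list of class `trial_result`: enrolled counts, interim
#'   decision and hazard-ratio estimates, calendar landmarks, total trial
#'   period, and rejection indicators
#' @export
run_trial <- function(design, stream, strategy = STRATEGIES, keep_data = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(design, "trial_design"))
  if (nrow(stream) != design$tss)
    stop_invalid("stream size must equal the design's planned sample size")

  if (strategy == "non_enriched") return(run_comparator(design, stream, keep_data))

  spec <- strategy_spec(strategy, design$stage1_target, design$decision_period)

  # Stage-1-only log to locate the interim cut (interim events are counted
  # within the stage-1 cohort, preserving the stage-wise p-value split).
  log1 <- apply_strategy(stream, spec, Inf, "futility", Inf)
  interim_time <- interim_trigger_time(log1, design$interim_events)

  int_O <- stage_data(log1, interim_time, "O", cohort = "stage1")
  int_P <- stage_data(log1, interim_time, "P", cohort = "stage1")
  hr_O <- safe_hazard_ratio(int_O)
  hr_P <- safe_hazard_ratio(int_P)
  decision <- interim_decision(hr_O, hr_P, design$eta_O, design$eta_P)
  decision_time <- interim_time + design$decision_period

  log <- apply_strategy(stream, spec, interim_time, decision, decision_time)
  if (decision == "enrich_P")
    log <- censor_negatives_on_enrichment(log, decision_time)

  final_time <- final_trigger_time(log, decision, design, decision_time)

  pvals <- list()
  if (decision == "futility") {
    fd <- closed_testing_decision(path = "futility", weights = design$weights,
                                  alpha = design$alpha)
  } else if (decision == "continue_O") {
    pvals <- list(
      p1_O = safe_logrank_p(stage_data(log, final_time, "O", "stage1")),
      p2_O = safe_logrank_p(stage_data(log, final_time, "O", "stage2")),
      p1_P = safe_logrank_p(stage_data(log, final_time, "P", "stage1")),
      p2_P = safe_logrank_p(stage_data(log, final_time, "P", "stage2")))
    fd <- closed_testing_decision(p1_O = pvals$p1_O, p2_O = pvals$p2_O,
                                  p1_P = pvals$p1_P, p2_P = pvals$p2_P,
                                  path = "continue_O",
                                  weights = design$weights, alpha = design$alpha)
  } else {
    pvals <- list(
      p1_O = safe_logrank_p(stage_data(log, final_time, "O", "stage1")),
      p1_P = safe_logrank_p(stage_data(log, final_time, "P", "stage1")),
      p2_P = safe_logrank_p(stage_data(log, final_time, "P", "stage2")))
    fd <- closed_testing_decision(p1_O = pvals$p1_O, p1_P = pvals$p1_P,
                                  p2_P = pvals$p2_P, path = "enrich_P",
                                  weights = design$weights, alpha = design$alpha)
  }

  res <- list(strategy = strategy,
              n_enrolled_O = sum(log$enrolled),
              n_enrolled_P = sum(log$enrolled & log$biomarker == "positive"),
              interim_decision = decision,
              interim_hr_O = hr_O, interim_hr_P = hr_P,
              interim_time = interim_time, decision_time = decision_time,
              final_time = final_time, total_period = final_time,
              rejected_O = fd$rejected_O, rejected_P = fd$rejected_P)
  if (keep_data) {
    res$log <- log
    res$pvals <- pvals
    res$final <- fd
  }
  structure(res, class = "trial_result")
}

# Non-enriched group-sequential comparator: no recruitment halt, one
# interim futility look (stop iff HR_O >= eta_O, no decision lag), final
# analysis at the fixed horizon R + F with a plain one-sided log-rank test
# of O at level alpha (no combination test, no multiplicity).
run_comparator <- function(design, stream, keep_data = FALSE) {
  spec <- strategy_spec("non_enriched", design$stage1_target, 0)
  log <- apply_strategy(stream, spec, Inf, "continue_O", Inf)
  interim_time <- interim_trigger_time(log, design$interim_events, cohort = NULL)
  int_O <- stage_data(log, interim_time, "O")
  hr_O <- safe_hazard_ratio(int_O)
  hr_P <- safe_hazard_ratio(stage_data(log, interim_time, "P"))

  if (hr_O >= design$eta_O) {
    # Futility stop: recruitment ends with the stop, later arrivals are
    # never enrolled.
    enrolled <- log$enrolled & log$enrollment_time <= interim_time
    res <- list(strategy = "non_enriched",
                n_enrolled_O = sum(enrolled),
                n_enrolled_P = sum(enrolled & log$biomarker == "positive"),
                interim_decision = "futility",
                interim_hr_O = hr_O, interim_hr_P = hr_P,
                interim_time = interim_time, decision_time = interim_time,
                final_time = interim_time, total_period = interim_time,
                rejected_O = FALSE, rejected_P = FALSE)
  } else {
    final_time <- design$R + design$F
    p <- safe_logrank_p(stage_data(log, final_time, "O"))
    res <- list(strategy = "non_enriched",
                n_enrolled_O = sum(log$enrolled),
                n_enrolled_P = sum(log$enrolled & log$biomarker == "positive"),
                interim_decision = "continue_O",
                interim_hr_O = hr_O, interim_hr_P = hr_P,
                interim_time = interim_time, decision_time = interim_time,
                final_time = final_time, total_period = final_time,
                rejected_O = as.numeric(p) < design$alpha, rejected_P = FALSE)
    if (keep_data) res$pvals <- list(p_final = p)
  }
  if (keep_data) res$log <- log
  structure(res, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial replicate (%s): %s at interim; %d enrolled (%d positive); total period %.3f\n",
              x$strategy, x$interim_decision, x$n_enrolled_O, x$n_enrolled_P,
              x$total_period))
  cat(sprintf("  interim HR: O %.3f, P %.3f; H0(O) %s, H0(P) %s\n",
              x$interim_hr_O, x$interim_hr_P,
              if (x$rejected_O) "rejected" else "retained",
              if (x$rejected_P) "rejected" else "retained"))
  invisible(x)
}
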