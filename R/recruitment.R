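# Recruitment strategies: mapping the prospective arrival stream to enrolled
# patients on the trial calendar.
#
# All strategies enroll the first `stage1_target` arrivals as the stage-1
# cohort. They differ in what happens between the end of stage-1 recruitment
# and the enactment of the interim decision (the "waiting window"), and in
# how the decision filters later arrivals:
#
#   typical      recruitment halts during the waiting window; pending
#                arrivals are deferred (the arrival schedule is shifted
#                forward by the halt duration) and then filtered by the
#                decision.
#   continued_O  arrivals of any biomarker status keep enrolling during the
#                waiting window; arrivals after the decision are filtered.
#   continued_P  only biomarker-positive arrivals enroll from the end of
#                stage-1 recruitment onward; after a continue-O decision
#                recruitment reopens to all of O (negatives skipped during
#                the window are lost, not replaced).
#   non_enriched group-sequential comparator: single recruitment phase, no
#                halt (interim handling lives in the trial engine).
#
# Decision filter for post-decision arrivals: continue_O enrolls everyone,
# enrich_P enrolls positives only, futility enrolls no one.

STRATEGIES <- c("typical", "continued_O", "continued_P", "non_enriched")

#' Recruitment strategy specification
#'
#' @param name one of `"typical"`, `"continued_O"`, `"continued_P"`,
#'   `"non_enriched"`
#' @param stage1_target number of stage-1 enrollees (half the planned total
#'   sample size at the default interim timing)
#' @param decision_period calendar lag from interim data cut to decision
#' @return an object of class `strategy_spec`
#' @export
strategy_spec <- function(name = STRATEGIES, stage1_target, decision_period = 0.2) {
  name <- match.arg(name)
  if (!is.numeric(stage1_target) || stage1_target < 1)
    stop_invalid("`stage1_target` must be a positive count")
  if (decision_period < 0) stop_invalid("`decision_period` must be >= 0")
  structure(list(name = name, stage1_target = as.integer(stage1_target),
                 decision_period = decision_period),
            class = "strategy_spec")
}

#' Apply a recruitment strategy to a patient stream
#'
#' Maps prospective arrivals to enrolled patients given the interim data-cut
#' time, the interim decision, and the calendar time at which the decision
#' takes effect. Returns the stream augmented with enrollment columns.
#'
#' @param stream a `patient_stream` (sorted by arrival)
#' @param spec a [strategy_spec()]
#' @param interim_cut_time calendar time of the interim data cut
#' @param decision interim decision: `"futility"`, `"continue_O"`,
#'   `"enrich_P"`
#' @param decision_time calendar time the decision is enacted
#'   (>= `interim_cut_time`)
#' @return an `enrollment_log`: the stream plus columns `enrolled`,
#'   `enrollment_time` (NA when not enrolled), `cohort`
#'   ("stage1"/"stage2"), `censoring_time` (Inf unless set later by
#'   enrichment censoring); the decision and strategy are stored as
#'   attributes
#' @export
apply_strategy <- function(stream, spec, interim_cut_time, decision,
                           decision_time) {
  stopifnot(inherits(spec, "strategy_spec"))
  decision <- match.arg(decision, c("futility", "continue_O", "enrich_P"))
  n <- nrow(stream)
  n1 <- spec$stage1_target
  if (n < n1) stop_invalid("patient stream shorter than the stage-1 target")
  if (is.unsorted(stream$arrival_time))
    stop_invalid("patient stream must be sorted by arrival time")
  if (decision_time < interim_cut_time)
    stop_invalid("`decision_time` must be >= `interim_cut_time`")

  log <- as.data.frame(stream)
  log$enrolled <- FALSE
  log$enrollment_time <- NA_real_
  log$cohort <- NA_character_

  # Stage-1 cohort: the first n1 arrivals, enrolled on arrival.
  log$enrolled[seq_len(n1)] <- TRUE
  log$enrollment_time[seq_len(n1)] <- log$arrival_time[seq_len(n1)]
  log$cohort[seq_len(n1)] <- "stage1"
  stage1_end <- log$arrival_time[n1]

  if (n > n1 && spec$name != "non_enriched") {
    rest <- (n1 + 1L):n
    arr <- log$arrival_time[rest]
    pos <- log$biomarker[rest] == "positive"
    post_ok <- switch(decision,
                      continue_O = rep(TRUE, length(rest)),
                      enrich_P = pos,
                      futility = rep(FALSE, length(rest)))
    if (spec$name == "typical") {
      # Frozen accrual: inter-arrival gaps preserved, schedule shifted by
      # the halt duration, all resumed arrivals land after the decision.
      shift <- max(0, decision_time - stage1_end)
      enr <- post_ok
      etime <- arr + shift
    } else if (spec$name == "continued_O") {
      in_window <- arr <= decision_time
      enr <- in_window | post_ok
      etime <- arr
    } else { # continued_P
      in_window <- arr > stage1_end & arr <= decision_time
      enr <- (in_window & pos) | (arr > decision_time & post_ok)
      etime <- arr
    }
    log$enrolled[rest] <- enr
    log$enrollment_time[rest][enr] <- etime[enr]
    log$cohort[rest][enr] <- "stage2"
  } else if (n > n1) {
    # Non-enriched comparator: everyone enrolls on arrival; the stage
    # labels are nominal (no stage-wise testing is done).
    rest <- (n1 + 1L):n
    log$enrolled[rest] <- TRUE
    log$enrollment_time[rest] <- log$arrival_time[rest]
    log$cohort[rest] <- "stage2"
  }

  log$censoring_time <- Inf
  structure(log,
            class = c("enrollment_log", "data.frame"),
            strategy = spec$name, decision = decision,
            interim_cut_time = interim_cut_time,
            decision_time = decision_time,
            stage1_end = stage1_end)
}

#' Curtail follow-up of biomarker-negative patients after enrichment
#'
#' When the interim decision restricts the trial to the biomarker-positive
#' subgroup, every enrolled biomarker-negative patient has follow-up
#' curtailed at the decision time: their `censoring_time` is set to
#' `decision_time`. Events observed before the decision are unaffected
#' (censoring cannot undo an observed event).
#'
#' @param log an `enrollment_log` whose decision is `"enrich_P"`
#' @param decision_time calendar censoring time for negatives
#' @return the updated `enrollment_log`
#' @export
censor_negatives_on_enrichment <- function(log, decision_time) {
  stopifnot(inherits(log, "enrollment_log"))
  if (!identical(attr(log, "decision"), "enrich_P"))
    stop_invalid("negatives may only be censored when the interim decision is enrich_P")
  idx <- log$enrolled & log$biomarker == "negative"
  log$censoring_time[idx] <- pmin(log$censoring_time[idx], decision_time)
  log
}

#' Anticipated minimum number of enrolled patients
#'
#' Closed-form lower bounds on the enrolled count per strategy, reached
#' when the interim decision is a futility stop: the typical strategy
#' enrolls only the stage-1 cohort; continued recruitment from the
#' biomarker-positive subgroup adds at most the positives among the
#' remaining prospective pool (all of them when follow-up exceeds
#' recruitment, so the whole pool arrives before the decision); continued
#' recruitment from the overall population adds the whole remaining pool.
#' Computed under the deterministic-prevalence assignment.
#'
#' @param design a [trial_design()]
#' @param strategy strategy name
#' @return integer patient count
#' @examples
#' d <- trial_design()
#' anticipated_min_enrolled(d, "typical")      # 165
#' anticipated_min_enrolled(d, "continued_P")  # 247
#' @export
anticipated_min_enrolled <- function(design, strategy = STRATEGIES) {
  strategy <- match.arg(strategy)
  n1 <- design$stage1_target
  bio <- deterministic_biomarker_sequence(design$tss, design$prevalence)
  switch(strategy,
         typical = n1,
         continued_P = n1 + sum(bio[(n1 + 1L):design$tss] == "positive"),
         continued_O = design$tss,
         non_enriched = design$tss)
}

#' Expected number of biomarker-positive patients under the non-enriched design
#'
#' The comparator enrolls the full planned sample, so the expected positive
#' count is prevalence times the total sample size.
#'
#' @param design a [trial_design()]
#' @return integer patient count
#' @export
expected_positives_non_enriched <- function(design) {
  as.integer(round_half_up(design$tss * design$prevalence))
}
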