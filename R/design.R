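# Trial design container and planning calculators.

#' Combination-test weights from planned stage information
#'
#' Pre-specified inverse-normal weights `w_k = sqrt(I_k / (I_1 + I_2))`,
#' where `I_k` is the planned number of events (information level)
#' attributed to stage k in the overall population. The weights are fixed at
#' design time and never re-estimated from observed events.
#'
#' @param planned_events_stage1,planned_events_stage2 planned event counts
#'   (>= 1)
#' @return an object of class `combination_weights` with elements `w1`,
#'   `w2`, `I1`, `I2`; `w1^2 + w2^2 = 1`
#' @examples
#' combination_weights(135, 135)  # w1 = w2 = sqrt(0.5)
#' @export
combination_weights <- function(planned_events_stage1, planned_events_stage2) {
  for (x in list(planned_events_stage1, planned_events_stage2))
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1)
      stop_invalid("planned stage event counts must be >= 1")
  tot <- planned_events_stage1 + planned_events_stage2
  structure(list(
    w1 = sqrt(planned_events_stage1 / tot),
    w2 = sqrt(planned_events_stage2 / tot),
    I1 = planned_events_stage1,
    I2 = planned_events_stage2
  ), class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat(sprintf("Combination weights: w1 = %.5f, w2 = %.5f (planned events %g / %g)\n",
              x$w1, x$w2, x$I1, x$I2))
  invisible(x)
}

#' Schoenfeld targeted sample size for a survival endpoint
#'
#' Evaluates the closed-form total sample size for a 1:1 two-arm comparison
#' with a one-sided level-`alpha` test and power `1 - beta`:
#'
#'   TSS = 4 (z_{1-alpha} + z_{1-beta})^2 / delta^2  x  2 / (S_E(t) + S_C(t))
#'
#' with `delta = log(hazard_ratio)` and survival probabilities of the two
#' arms at the evaluation time. The first factor is the required event
#' count; the second converts events to patients. `conversion =
#' "event_probability"` replaces the printed second factor by
#' `1 / (1 - (S_E + S_C)/2)` (the usual division by the average event
#' probability); the printed form is the default.
#'
#' @param alpha one-sided significance level
#' @param beta type-II error (power = 1 - beta)
#' @param hazard_ratio planned hazard ratio, > 0 and != 1
#' @param surv_E,surv_C survival probabilities of the experimental and
#'   control arms at the evaluation time
#' @param conversion events-to-patients conversion: "printed" (default) or
#'   "event_probability"
#' @param round_even if TRUE, round the patient count up to an even integer
#'   (exact 1:1 allocation); default plain ceiling
#' @return list with `tss` (integer count), `tss_unrounded`, and
#'   `required_events` (the first factor)
#' @examples
#' schoenfeld_tss(0.025, 0.2, 0.5, surv_E = 0.2^0.5, surv_C = 0.2)
#' @export
schoenfeld_tss <- function(alpha, beta, hazard_ratio, surv_E, surv_C,
                           conversion = c("printed", "event_probability"),
                           round_even = FALSE) {
  conversion <- match.arg(conversion)
  check_prob(alpha, "alpha"); check_prob(beta, "beta")
  check_prob(surv_E, "surv_E"); check_prob(surv_C, "surv_C")
  check_pos(hazard_ratio, "hazard_ratio")
  if (hazard_ratio == 1)
    stop_invalid("`hazard_ratio` = 1 gives delta = 0: sample size is undefined")
  delta <- log(hazard_ratio)
  events <- 4 * (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta))^2 / delta^2
  factor2 <- switch(conversion,
                    printed = 2 / (surv_E + surv_C),
                    event_probability = 1 / (1 - (surv_E + surv_C) / 2))
  raw <- events * factor2
  n <- ceiling(raw)
  if (round_even && n %% 2 == 1) n <- n + 1
  list(tss = as.integer(n), tss_unrounded = raw, required_events = events)
}

#' Hazard-ratio scenarios of the simulation study
#'
#' Five planning scenarios: the hazard ratio in the biomarker-positive
#' subgroup is 0.50 throughout, while the biomarker-negative hazard ratio
#' ranges from equally beneficial (0.50) to harmful (1.43).
#'
#' @param scenario integer in 1..5
#' @return list with `hr_positive` and `hr_negative`
#' @export
scenario_hazard_ratios <- function(scenario) {
  hr_N <- c(0.50, 0.90, 1.00, 1.11, 1.43)
  if (!scenario %in% 1:5) stop_invalid("`scenario` must be an integer in 1..5")
  list(hr_positive = 0.50, hr_negative = hr_N[scenario])
}

#' Two-stage adaptive enrichment trial design
#'
#' Bundles every design constant of the simulated trial: the planned total
#' sample size and event target, the interim timing, the decision
#' thresholds, the accrual pattern, and the survival assumptions. Derived
#' quantities (stage-1 cohort size, interim event target, combination
#' weights, control hazard) are computed here once.
#'
#' The stage-1 recruitment target is tied to the interim timing:
#' `round_half_up(interim_fraction * tss)` patients are recruited in stage 1
#' and the interim analysis is triggered by
#' `round_half_up(interim_fraction * total_events)` events among them, so at
#' the default 50% timing 165 patients yield the 135-event interim look.
#'
#' @param tss planned total sample size in the overall population
#' @param total_events planned event count triggering the final analysis
#' @param interim_fraction fraction of `total_events` at the interim look
#' @param alpha one-sided significance level
#' @param eta_O,eta_P interim hazard-ratio thresholds for the overall and
#'   biomarker-positive populations
#' @param R recruitment duration
#' @param F follow-up duration (calibration horizon of the survival model)
#' @param decision_period calendar lag between the interim data cut and the
#'   enactment of the decision
#' @param prevalence proportion of biomarker-positives in the overall
#'   population
#' @param hr_positive,hr_negative true hazard ratios of the simulated
#'   scenario
#' @param control_survival control-arm survival probability at `F`
#' @param accrual "uniform" or "trunc_exp"
#' @param gamma truncated-exponential shape (required when
#'   `accrual = "trunc_exp"`)
#' @param biomarker_mode,allocation passed to [generate_patient_stream()]
#' @return an object of class `trial_design`
#' @examples
#' trial_design(R = 6, F = 2, hr_negative = 1.43)
#' @export
trial_design <- function(tss = 330, total_events = 270, interim_fraction = 0.5,
                         alpha = 0.025, eta_O = 1.00, eta_P = 1.00,
                         R = 2, F = 4, decision_period = 0.2,
                         prevalence = 0.5,
                         hr_positive = 0.5, hr_negative = 1.0,
                         control_survival = 0.2,
                         accrual = c("uniform", "trunc_exp"), gamma = NULL,
                         biomarker_mode = "deterministic",
                         allocation = "deterministic") {
  accrual <- match.arg(accrual)
  check_prob(alpha, "alpha"); check_prob(interim_fraction, "interim_fraction")
  check_prob(prevalence, "prevalence")
  check_pos(eta_O, "eta_O"); check_pos(eta_P, "eta_P")
  check_pos(R, "R"); check_pos(F, "F")
  if (decision_period < 0) stop_invalid("`decision_period` must be >= 0")
  if (total_events > tss) stop_invalid("`total_events` cannot exceed `tss`")
  if (alpha >= 0.5) stop_invalid("`alpha` must be below 0.5 (one-sided)")

  pattern <- if (accrual == "uniform") accrual_uniform(R) else accrual_trunc_exp(R, gamma)
  model <- survival_model(control_survival, F, hr_positive, hr_negative)
  interim_events <- as.integer(round_half_up(interim_fraction * total_events))
  stage1_target <- as.integer(round_half_up(interim_fraction * tss))

  structure(list(
    tss = as.integer(tss), total_events = as.integer(total_events),
    interim_fraction = interim_fraction, interim_events = interim_events,
    stage1_target = stage1_target,
    alpha = alpha, eta_O = eta_O, eta_P = eta_P,
    R = R, F = F, decision_period = decision_period,
    prevalence = prevalence,
    model = model, pattern = pattern,
    biomarker_mode = biomarker_mode, allocation = allocation,
    weights = combination_weights(interim_events,
                                  max(total_events - interim_events, 1L))
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-stage adaptive enrichment trial design\n")
  cat(sprintf("  TSS %d (stage 1: %d), final analysis at %d events, interim at %d (%.0f%%)\n",
              x$tss, x$stage1_target, x$total_events, x$interim_events,
              100 * x$interim_fraction))
  cat(sprintf("  one-sided alpha %.4g; interim thresholds eta_O = %g, eta_P = %g\n",
              x$alpha, x$eta_O, x$eta_P))
  cat(sprintf("  R = %g, F = %g, decision period %g; prevalence %.0f%%\n",
              x$R, x$F, x$decision_period, 100 * x$prevalence))
  cat(sprintf("  scenario hazard ratios: %.3g (P), %.3g (N); accrual %s\n",
              x$model$hr_positive, x$model$hr_negative, x$pattern$kind))
  invisible(x)
}

# Fresh stream drawn for one replicate under a design.
design_stream <- function(design, seed = NULL) {
  generate_patient_stream(design$tss, design$model, design$pattern,
                          prevalence = design$prevalence,
                          biomarker_mode = design$biomarker_mode,
                          allocation = design$allocation,
                          seed = seed)
}
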