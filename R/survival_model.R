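# Exponential survival model calibrated to a stated control-arm survival
# probability at the end of the follow-up period, with proportional hazards
# in the biomarker-positive (P) and biomarker-negative (N) subgroups.

#' Exponential hazard from a survival probability
#'
#' Solves `exp(-lambda * horizon) = survival_prob` for the constant hazard
#' `lambda`. Used to calibrate the control-arm event-time distribution to a
#' planned survival probability at the end of follow-up (e.g. 20% at F).
#'
#' @param survival_prob survival probability in (0, 1)
#' @param horizon positive time at which `survival_prob` holds
#' @return the hazard rate `-log(survival_prob) / horizon`
#' @examples
#' hazard_from_survival(0.2, 2)   # 0.80472
#' @export
hazard_from_survival <- function(survival_prob, horizon) {
  check_prob(survival_prob, "survival_prob")
  check_pos(horizon, "horizon")
  -log(survival_prob) / horizon
}

#' Experimental-arm survival under proportional hazards
#'
#' With exponential event times and hazard ratio `hr`, the experimental-arm
#' survival at any time equals the control survival raised to `hr`.
#'
#' @param control_survival control-arm survival probability in (0, 1)
#' @param hr hazard ratio (> 0) of experimental vs control
#' @return experimental-arm survival probability `control_survival^hr`
#' @examples
#' experimental_survival_at_F(0.2, 0.5)  # 0.4472
#' @export
experimental_survival_at_F <- function(control_survival, hr) {
  check_prob(control_survival, "control_survival")
  check_pos(hr, "hr")
  control_survival^hr
}

#' Survival model for the simulated trial population
#'
#' Exponential event times in all four arm-by-biomarker cells. The control
#' hazard is calibrated so that control-arm survival at the end of follow-up
#' `follow_up_F` equals `control_survival_at_F`; the experimental hazard in
#' subgroup g is `control_hazard * hr_g`.
#'
#' @param control_survival_at_F control survival probability at `follow_up_F`
#' @param follow_up_F follow-up duration (same abstract time unit as
#'   recruitment; interpretable as years)
#' @param hr_positive hazard ratio (experimental vs control) in the
#'   biomarker-positive subgroup
#' @param hr_negative hazard ratio in the biomarker-negative subgroup
#' @return an object of class `survival_model`
#' @examples
#' survival_model(0.2, 2, hr_positive = 0.5, hr_negative = 1.43)
#' @export
survival_model <- function(control_survival_at_F = 0.2, follow_up_F = 2,
                           hr_positive = 0.5, hr_negative = 1) {
  check_pos(hr_positive, "hr_positive")
  check_pos(hr_negative, "hr_negative")
  lambda <- hazard_from_survival(control_survival_at_F, follow_up_F)
  structure(list(
    control_survival_at_F = control_survival_at_F,
    follow_up_F = follow_up_F,
    hr_positive = hr_positive,
    hr_negative = hr_negative,
    control_hazard = lambda,
    delta_positive = log(hr_positive),
    delta_negative = log(hr_negative)
  ), class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat("Exponential survival model\n")
  cat(sprintf("  control survival %.0f%% at F = %g (hazard %.5f)\n",
              100 * x$control_survival_at_F, x$follow_up_F, x$control_hazard))
  cat(sprintf("  hazard ratio: %.3f (positive), %.3f (negative)\n",
              x$hr_positive, x$hr_negative))
  invisible(x)
}

# Event hazard for one patient given arm and biomarker status.
patient_hazard <- function(model, arm, biomarker) {
  hr <- ifelse(arm == "experimental",
               ifelse(biomarker == "positive", model$hr_positive, model$hr_negative),
               1)
  model$control_hazard * hr
}
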