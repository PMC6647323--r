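# Stage-wise survival statistics and the confirmatory testing machinery.
#
# Stage data are plain data.frames with columns `time` (time on study),
# `event` (0/1 or logical), and `arm` ("experimental"/"control"), optionally
# `biomarker`. Stage-wise tests are one-sided log-rank tests oriented so
# that small p-values favor the experimental arm; interim decisions use Cox
# partial-likelihood hazard-ratio estimates.

ARM_LEVELS <- c("control", "experimental")

validate_stage_data <- function(data) {
  if (!is.data.frame(data) || !all(c("time", "event", "arm") %in% names(data)))
    stop_invalid("stage data must be a data.frame with columns time, event, arm")
  if (any(data$time < 0)) stop_invalid("time on study must be >= 0")
  if (!all(data$arm %in% ARM_LEVELS))
    stop_invalid("`arm` must be 'experimental' or 'control'")
  data$event <- as.integer(as.logical(data$event))
  data$arm <- factor(data$arm, levels = ARM_LEVELS)
  data
}

#' One-sided log-rank p-value
#'
#' Standard (unweighted) log-rank test of experimental vs control, returned
#' as the one-sided p-value `1 - pnorm(Z)` where `Z > 0` when the
#' experimental arm has fewer events than expected under the null (i.e.
#' small p favors the experimental arm).
#'
#' @param data stage data: data.frame with `time`, `event`, `arm`
#' @return one-sided p-value, with the standardized statistic attached as
#'   attribute `"z"`
#' @export
one_sided_logrank_p <- function(data) {
  data <- validate_stage_data(data)
  if (length(unique(data$arm[!is.na(data$arm)])) < 2L ||
      !all(table(data$arm) >= 1L))
    stop_invalid("log-rank test requires at least one record in each arm")
  if (sum(data$event) < 1L)
    stop_invalid("log-rank test requires at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = data)
  v <- sd$var[1, 1]
  if (!is.finite(v) || v <= 0)
    stop_invalid("log-rank variance is zero; test undefined on these data")
  z <- (sd$exp[2] - sd$obs[2]) / sqrt(v)  # > 0 when experimental has fewer events
  p <- 1 - stats::pnorm(z)
  attr(p, "z") <- unname(z)
  p
}

# Engine-internal: neutral p = 0.5 when a stage test is undefined (empty
# cohort, single arm, no events). Flagged via attribute.
safe_logrank_p <- function(data) {
  out <- tryCatch(one_sided_logrank_p(data), error = function(e) {
    p <- 0.5
    attr(p, "degenerate") <- conditionMessage(e)
    p
  })
  out
}

#' Cox proportional-hazards estimate of the hazard ratio
#'
#' Maximum partial-likelihood estimate (Efron tie handling) of the
#' experimental-vs-control hazard ratio; values below 1 favor the
#' experimental arm. When the likelihood is monotone (all events in one
#' arm) the estimate diverges; it is then returned at the configured cap
#' (`cap` if events are all experimental, `1/cap` if all control) with a
#' warning.
#'
#' @param data stage data: data.frame with `time`, `event`, `arm`
#' @param cap positive cap for divergent estimates (default 1e3)
#' @return hazard-ratio estimate in `[1/cap, cap]`
#' @export
estimate_hazard_ratio <- function(data, cap = 1e3) {
  data <- validate_stage_data(data)
  check_pos(cap, "cap")
  if (!all(table(data$arm) >= 1L))
    stop_invalid("hazard-ratio estimation requires both arms present")
  ev <- tapply(data$event, data$arm, sum)
  ev[is.na(ev)] <- 0
  if (sum(ev) < 1L) stop_invalid("hazard-ratio estimation requires at least one event")
  if (ev[["control"]] == 0L) {
    warning("all events in the experimental arm: monotone likelihood, estimate capped",
            call. = FALSE)
    return(cap)
  }
  if (ev[["experimental"]] == 0L) {
    warning("all events in the control arm: monotone likelihood, estimate capped",
            call. = FALSE)
    return(1 / cap)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = data,
                         ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  hr <- exp(unname(stats::coef(fit)[1]))
  if (!is.finite(hr) || hr > cap || hr < 1 / cap) {
    warning("hazard-ratio estimate beyond cap; returning capped value", call. = FALSE)
    hr <- min(max(hr, 1 / cap, na.rm = TRUE), cap)
  }
  hr
}

#' Interim decision rule on hazard-ratio estimates
#'
#' Compares interim hazard-ratio estimates for the overall population (O)
#' and the biomarker-positive subgroup (P) against thresholds:
#' (i) futility stop if both estimates are at/above their thresholds,
#' (ii) continue with O if the O estimate is below `eta_O` (regardless of
#' P), (iii) enrich to P if the O estimate is at/above `eta_O` but the P
#' estimate is below `eta_P`. An estimate exactly at its threshold counts
#' as "not beneficial".
#'
#' @param hr_O,hr_P interim hazard-ratio estimates (> 0)
#' @param eta_O,eta_P decision thresholds (> 0), both 1.00 in the reference
#'   configuration
#' @return one of `"futility"`, `"continue_O"`, `"enrich_P"`
#' @examples
#' interim_decision(1.2, 1.1)   # futility
#' interim_decision(0.9, 1.3)   # continue_O
#' interim_decision(1.05, 0.8)  # enrich_P
#' @export
interim_decision <- function(hr_O, hr_P, eta_O = 1.00, eta_P = 1.00) {
  for (nm in c("hr_O", "hr_P", "eta_O", "eta_P"))
    check_pos(get(nm), nm)
  if (hr_O < eta_O) "continue_O"
  else if (hr_P < eta_P) "enrich_P"
  else "futility"
}

#' Weighted inverse-normal combination test
#'
#' Combines independent stage-wise p-values as
#' `C = w1 * qnorm(1 - p1) + w2 * qnorm(1 - p2)` and rejects when
#' `C > qnorm(1 - alpha)`. Equivalently, the combined p-value
#' `1 - pnorm(C)` is below `alpha`. p-values at 0 or 1 are clipped to the
#' open interval with a warning.
#'
#' @param p1,p2 stage-1 and stage-2 p-values in (0, 1)
#' @param weights a [combination_weights()] object
#' @param alpha one-sided significance level
#' @return list with `statistic`, `p_value`, `critical`, `reject`
#' @examples
#' w <- combination_weights(135, 135)
#' combination_statistic(0.025, 0.025, w)  # C = 2.7718, rejected
#' @export
combination_statistic <- function(p1, p2, weights, alpha = 0.025) {
  stopifnot(inherits(weights, "combination_weights"))
  check_prob(alpha, "alpha")
  p1 <- clip_p(p1); p2 <- clip_p(p2)
  C <- weights$w1 * stats::qnorm(1 - p1) + weights$w2 * stats::qnorm(1 - p2)
  crit <- stats::qnorm(1 - alpha)
  list(statistic = unname(C), p_value = 1 - stats::pnorm(unname(C)),
       critical = crit, reject = unname(C) > crit)
}

#' Hochberg p-value for a two-hypothesis intersection
#'
#' `min(2 * min(p_a, p_b), max(p_a, p_b))`, capped at 1: the Hochberg
#' step-up adjustment for the intersection of two elementary hypotheses.
#'
#' @param p_O,p_P elementary p-values (vectors recycle)
#' @return intersection p-value(s)
#' @examples
#' hochberg_intersection_p(0.01, 0.03)  # 0.02
#' @export
hochberg_intersection_p <- function(p_O, p_P) {
  if (any(c(p_O, p_P) < 0 | c(p_O, p_P) > 1))
    stop_invalid("p-values must lie in [0, 1]")
  pmin(pmin(2 * pmin(p_O, p_P), pmax(p_O, p_P)), 1)
}

#' Closed-testing decision for the two elementary hypotheses
#'
#' Applies the closure principle with Hochberg intersection p-values and
#' the weighted inverse-normal combination test, along the realized
#' decision path:
#'
#' * `continue_O`: H0(O) is rejected iff the intersection combination test
#'   and the O combination test both pass; H0(P) iff the intersection and
#'   the P combination tests both pass.
#' * `enrich_P`: only H0(P) can be rejected, iff
#'   `C(p1_OP, p2_P)` and `C(p1_P, p2_P)` both pass (the stage-2
#'   intersection p-value reduces to the P p-value once N is terminated).
#' * `futility`: nothing is rejected.
#'
#' @param p1_O,p2_O stage-wise p-values for the overall population (stage 2
#'   required on the continue_O path only)
#' @param p1_P,p2_P stage-wise p-values for the biomarker-positive subgroup
#' @param path realized decision path: "continue_O", "enrich_P", "futility"
#' @param weights a [combination_weights()] object
#' @param alpha one-sided significance level
#' @return list of class `final_decision`: `rejected_O`, `rejected_P`,
#'   `path`, and a `tests` list with the component combination tests
#' @export
closed_testing_decision <- function(p1_O = NULL, p2_O = NULL,
                                    p1_P = NULL, p2_P = NULL,
                                    path = c("continue_O", "enrich_P", "futility"),
                                    weights, alpha = 0.025) {
  path <- match.arg(path)
  if (path == "futility")
    return(structure(list(rejected_O = FALSE, rejected_P = FALSE,
                          path = path, tests = list()),
                     class = "final_decision"))
  need <- switch(path,
                 continue_O = c("p1_O", "p2_O", "p1_P", "p2_P"),
                 enrich_P = c("p1_O", "p1_P", "p2_P"))
  for (nm in need)
    if (is.null(get(nm)))
      stop_invalid(sprintf("`%s` is required on the %s path", nm, path))

  p1_OP <- hochberg_intersection_p(p1_O, p1_P)
  if (path == "continue_O") {
    p2_OP <- hochberg_intersection_p(p2_O, p2_P)
    t_int <- combination_statistic(p1_OP, p2_OP, weights, alpha)
    t_O <- combination_statistic(p1_O, p2_O, weights, alpha)
    t_P <- combination_statistic(p1_P, p2_P, weights, alpha)
    out <- list(rejected_O = t_int$reject && t_O$reject,
                rejected_P = t_int$reject && t_P$reject,
                path = path,
                tests = list(intersection = t_int, O = t_O, P = t_P))
  } else {
    t_int <- combination_statistic(p1_OP, p2_P, weights, alpha)
    t_P <- combination_statistic(p1_P, p2_P, weights, alpha)
    out <- list(rejected_O = FALSE,
                rejected_P = t_int$reject && t_P$reject,
                path = path,
                tests = list(intersection = t_int, P = t_P))
  }
  structure(out, class = "final_decision")
}

#' @export
print.final_decision <- function(x, ...) {
  cat(sprintf("Closed testing on the %s path: H0(O) %s, H0(P) %s\n", x$path,
              if (x$rejected_O) "rejected" else "retained",
              if (x$rejected_P) "rejected" else "retained"))
  invisible(x)
}
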