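# Monte-Carlo driver: replicate loop with common random numbers across
# strategies, operating-characteristic summaries, and the interim-timing
# sensitivity study.

#' Run a Monte-Carlo simulation of the trial design
#'
#' Executes `n_reps` replicates. Each replicate draws one patient stream
#' from a replicate-indexed child seed and runs every requested strategy on
#' that same stream (common random numbers), so strategy comparisons are
#' paired. Fully reproducible given `master_seed`.
#'
#' @param design a [trial_design()]
#' @param strategies character vector of strategy names
#' @param n_reps number of replicates (>= 1)
#' @param master_seed integer master seed
#' @return data.frame of class `sim_results`, one row per replicate per
#'   strategy, with the design stored as an attribute
#' @export
run_simulation <- function(design,
                           strategies = c("typical", "continued_O",
                                          "continued_P", "non_enriched"),
                           n_reps = 1000, master_seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  strategies <- match.arg(strategies, STRATEGIES, several.ok = TRUE)
  if (n_reps < 1) stop_invalid("`n_reps` must be >= 1")
  seeds <- child_seeds(master_seed, n_reps)

  fields <- c("n_enrolled_O", "n_enrolled_P", "total_period", "interim_time",
              "decision_time", "final_time", "interim_hr_O", "interim_hr_P")
  rows <- vector("list", n_reps * length(strategies))
  k <- 0L
  for (r in seq_len(n_reps)) {
    stream <- design_stream(design, seed = seeds[r])
    for (s in strategies) {
      res <- suppressWarnings(run_trial(design, stream, s))
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = r, strategy = s,
        interim_decision = res$interim_decision,
        rejected_O = res$rejected_O, rejected_P = res$rejected_P,
        as.list(unlist(res[fields])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sim_results", "data.frame"),
            design = design, master_seed = master_seed)
}

#' Operating characteristics of a simulation run
#'
#' Per-strategy summaries: patient-number distribution (mean/min/max for
#' the overall and biomarker-positive counts), total-trial-period
#' distribution (mean and quartiles), interim decision probabilities,
#' rejection probabilities for the two elementary hypotheses, and the bias
#' and RMSE of the interim log hazard-ratio estimate for the
#' biomarker-positive subgroup against the design's true value.
#'
#' @param results a `sim_results` data.frame from [run_simulation()]
#' @param design the design used (defaults to the attribute stored on
#'   `results`)
#' @return data.frame, one row per strategy
#' @export
operating_characteristics <- function(results, design = attr(results, "design")) {
  stopifnot(is.data.frame(results))
  true_log_hr_P <- log(design$model$hr_positive)
  split_res <- split(results, results$strategy)
  out <- lapply(split_res, function(d) {
    err <- log(d$interim_hr_P) - true_log_hr_P
    err <- err[is.finite(err)]
    data.frame(
      strategy = d$strategy[1], n_reps = nrow(d),
      mean_n_O = mean(d$n_enrolled_O), min_n_O = min(d$n_enrolled_O),
      max_n_O = max(d$n_enrolled_O),
      mean_n_P = mean(d$n_enrolled_P), min_n_P = min(d$n_enrolled_P),
      max_n_P = max(d$n_enrolled_P),
      mean_period = mean(d$total_period),
      q25_period = unname(stats::quantile(d$total_period, 0.25)),
      median_period = stats::median(d$total_period),
      q75_period = unname(stats::quantile(d$total_period, 0.75)),
      p_futility = mean(d$interim_decision == "futility"),
      p_continue_O = mean(d$interim_decision == "continue_O"),
      p_enrich_P = mean(d$interim_decision == "enrich_P"),
      p_reject_O = mean(d$rejected_O), p_reject_P = mean(d$rejected_P),
      fwer = mean(d$rejected_O | d$rejected_P),
      interim_loghr_P_bias = mean(err),
      interim_loghr_P_rmse = sqrt(mean(err^2)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interim-timing sensitivity study
#'
#' Re-runs the simulation with the interim look placed at each requested
#' fraction of the planned events (the stage-1 recruitment target scales
#' with the fraction), summarizing the accuracy of the interim
#' biomarker-positive log hazard ratio (bias, RMSE) and the expected
#' enrolled numbers per strategy. The same master seed is used for every
#' fraction, so comparisons across fractions are paired.
#'
#' @param design a [trial_design()]; its `interim_fraction` is overridden
#' @param fractions interim timings as fractions of the planned events
#' @param strategies strategies to run
#' @param n_reps replicates per fraction
#' @param master_seed integer master seed
#' @return data.frame, one row per fraction per strategy, with columns for
#'   expected patient numbers and interim log-HR bias/RMSE
#' @export
interim_timing_study <- function(design, fractions = c(0.25, 0.50, 0.75),
                                 strategies = c("typical", "continued_O",
                                                "continued_P"),
                                 n_reps = 1000, master_seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  if (any(fractions <= 0 | fractions >= 1))
    stop_invalid("interim fractions must lie in (0, 1)")
  out <- lapply(fractions, function(f) {
    d <- trial_design(
      tss = design$tss, total_events = design$total_events,
      interim_fraction = f, alpha = design$alpha,
      eta_O = design$eta_O, eta_P = design$eta_P,
      R = design$R, F = design$F, decision_period = design$decision_period,
      prevalence = design$prevalence,
      hr_positive = design$model$hr_positive,
      hr_negative = design$model$hr_negative,
      control_survival = design$model$control_survival_at_F,
      accrual = if (design$pattern$kind == "uniform") "uniform" else "trunc_exp",
      gamma = design$pattern$gamma,
      biomarker_mode = design$biomarker_mode, allocation = design$allocation)
    res <- run_simulation(d, strategies, n_reps, master_seed)
    oc <- operating_characteristics(res, d)
    cbind(interim_fraction = f, oc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write simulation results as a delimited table with a documented header
#'
#' @param results a `sim_results` data.frame
#' @param path output file
#' @param sep field separator
#' @export
write_results <- function(results, path, sep = "\t") {
  design <- attr(results, "design")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# enrichsim results, schema v1: one row per replicate per strategy",
    sprintf("# master_seed=%s", attr(results, "master_seed")),
    if (!is.null(design))
      sprintf("# design: tss=%d total_events=%d interim_fraction=%g alpha=%g eta_O=%g eta_P=%g R=%g F=%g decision_period=%g prevalence=%g hr_positive=%g hr_negative=%g accrual=%s gamma=%s",
              design$tss, design$total_events, design$interim_fraction,
              design$alpha, design$eta_O, design$eta_P, design$R, design$F,
              design$decision_period, design$prevalence,
              design$model$hr_positive, design$model$hr_negative,
              design$pattern$kind,
              if (is.null(design$pattern$gamma)) "NA" else design$pattern$gamma)
  ), con)
  utils::write.table(as.data.frame(results), con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design (and simulation settings) from a YAML config file
#'
#' The config mirrors the [trial_design()] arguments under a `design`
#' section, with an optional `simulation` section (`n_reps`, `master_seed`,
#' `strategies`).
#'
#' @param path path to a YAML file
#' @return list with elements `design` (a `trial_design`) and `simulation`
#'   (a list, possibly empty)
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design)) stop_invalid("config must contain a `design` section")
  design <- do.call(trial_design, cfg$design)
  list(design = design, simulation = cfg$simulation %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
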