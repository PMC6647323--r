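# Per-replicate patient streams: the full roster of prospective patients a
# trial could screen, in arrival order, with biomarker status, randomized
# arm, and a latent exponential event time. Which of these patients are
# actually enrolled (and when) is decided later by a recruitment strategy.

#' Deterministic biomarker sequence
#'
#' Assigns biomarker status in arrival order so that every prefix carries
#' the prevalence as exactly as possible: patient i is positive iff the
#' running quota `round_half_up(i * prevalence)` increments at i. For
#' prevalence 0.5 this is strict alternation starting with a positive, so
#' every consecutive pair of arrivals contains exactly one positive and an
#' odd prefix of length 165 contains 83 positives.
#'
#' @param n number of patients
#' @param prevalence proportion of biomarker-positives in the overall
#'   population
#' @return character vector of "positive"/"negative"
#' @export
deterministic_biomarker_sequence <- function(n, prevalence = 0.5) {
  check_prob(prevalence, "prevalence")
  quota <- round_half_up(seq_len(n) * prevalence)
  ifelse(diff(c(0, quota)) > 0, "positive", "negative")
}

#' Generate a seeded patient stream
#'
#' Produces the roster of `n` prospective patients: sorted arrival times
#' drawn from the accrual pattern, biomarker status, 1:1 randomized arm, and
#' a latent exponential event time (measured from enrollment) with the
#' hazard of the patient's arm-by-biomarker cell.
#'
#' Biomarker status: `"deterministic"` (default) uses
#' [deterministic_biomarker_sequence()], which pins the positive count in
#' every prefix (needed to reproduce printed patient minima such as 165/2
#' rounded prefixes); `"bernoulli"` draws iid indicators with the given
#' prevalence. Treatment allocation: `"deterministic"` alternates
#' experimental/control within each biomarker stratum in arrival order
#' (permuted blocks of 2, exact balance); `"simple"` randomizes each patient
#' independently.
#'
#' @param n number of prospective patients (the planned total sample size)
#' @param model a [survival_model()]
#' @param pattern an accrual pattern ([accrual_uniform()] or
#'   [accrual_trunc_exp()])
#' @param prevalence proportion of biomarker-positives
#' @param biomarker_mode "deterministic" or "bernoulli"
#' @param allocation "deterministic" or "simple"
#' @param seed optional integer; if given, the stream is a pure function of
#'   it
#' @return a `data.frame` of class `patient_stream` with columns `id`,
#'   `arrival_time`, `biomarker`, `arm`, `latent_event_time`
#' @export
generate_patient_stream <- function(n, model, pattern, prevalence = 0.5,
                                    biomarker_mode = c("deterministic", "bernoulli"),
                                    allocation = c("deterministic", "simple"),
                                    seed = NULL) {
  stopifnot(inherits(model, "survival_model"), inherits(pattern, "accrual_pattern"))
  biomarker_mode <- match.arg(biomarker_mode)
  allocation <- match.arg(allocation)
  if (!is.null(seed)) set.seed(as.integer(seed))

  arrival <- sample_arrival_times(n, pattern)
  biomarker <- switch(biomarker_mode,
    deterministic = deterministic_biomarker_sequence(n, prevalence),
    bernoulli = ifelse(stats::rbinom(n, 1L, prevalence) == 1L, "positive", "negative"))

  arm <- character(n)
  if (allocation == "deterministic") {
    for (b in c("positive", "negative")) {
      idx <- which(biomarker == b)
      arm[idx] <- rep_len(c("experimental", "control"), length(idx))
    }
  } else {
    arm <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "experimental", "control")
  }

  lambda <- patient_hazard(model, arm, biomarker)
  latent <- stats::rexp(n, rate = lambda)

  structure(data.frame(
    id = seq_len(n),
    arrival_time = arrival,
    biomarker = biomarker,
    arm = arm,
    latent_event_time = latent,
    stringsAsFactors = FALSE
  ), class = c("patient_stream", "data.frame"))
}

#' Write a patient stream as a delimited table
#'
#' @param stream a `patient_stream`
#' @param path output file
#' @param sep field separator
#' @export
write_patient_stream <- function(stream, path, sep = "\t") {
  utils::write.table(as.data.frame(stream), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
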