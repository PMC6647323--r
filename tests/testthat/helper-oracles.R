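# Independent oracles for the stage-wise survival statistics, built from
# first principles (risk-set tables, grid maximization), deliberately not
# sharing code with the package implementation.

# Log-rank statistic from an explicit risk-set table. Returns the
# standardized Z oriented so Z > 0 favors the experimental arm, and the
# one-sided p-value.
logrank_oracle <- function(time, event, arm) {
  stopifnot(length(time) == length(event), length(time) == length(arm))
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_e <- sum(at_risk & arm == "experimental")
    d <- sum(time == t & event == 1)
    d_e <- sum(time == t & event == 1 & arm == "experimental")
    O <- O + d_e
    E <- E + d * n_e / n
    if (n > 1) V <- V + d * n_e * (n - n_e) * (n - d) / (n^2 * (n - 1))
  }
  z <- (E - O) / sqrt(V)
  list(z = z, p = 1 - pnorm(z))
}

# Cox partial-likelihood estimate by grid/line maximization (Breslow form;
# equals Efron when event times are distinct).
cox_grid_oracle <- function(time, event, arm) {
  x <- as.numeric(arm == "experimental")
  negloglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    -ll
  }
  exp(optimize(negloglik, c(-10, 10), tol = 1e-9)$minimum)
}

# Small two-arm stage-data fixture with distinct times.
make_stage_data <- function(time, event, arm) {
  data.frame(time = time, event = event, arm = arm, stringsAsFactors = FALSE)
}

# Stage data drawn from exponential arms (no censoring).
sim_two_arm_exp <- function(n_per_arm, rate_control, rate_exp) {
  data.frame(
    time = c(rexp(n_per_arm, rate_control), rexp(n_per_arm, rate_exp)),
    event = 1L,
    arm = rep(c("control", "experimental"), each = n_per_arm),
    stringsAsFactors = FALSE)
}

# Hand-built patient stream (already sorted by arrival) for recruitment
# tests, mirroring the deterministic biomarker/allocation rules.
make_stream <- function(n, arrival, seed = 1, prevalence = 0.5,
                        latent = NULL) {
  set.seed(seed)
  biomarker <- enrichsim::deterministic_biomarker_sequence(n, prevalence)
  arm <- character(n)
  for (b in c("positive", "negative")) {
    idx <- which(biomarker == b)
    arm[idx] <- rep_len(c("experimental", "control"), length(idx))
  }
  if (is.null(latent)) latent <- rexp(n, rate = 0.8)
  structure(data.frame(
    id = seq_len(n), arrival_time = sort(arrival), biomarker = biomarker,
    arm = arm, latent_event_time = latent, stringsAsFactors = FALSE
  ), class = c("patient_stream", "data.frame"))
}
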