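# Patient accrual over the recruitment window [0, R]: uniform, or the
# truncated exponential with CDF F(t) = (1 - exp(-gamma t)) / (1 - exp(-gamma R)).
# gamma > 0 gives convex (front-loaded) accrual, gamma < 0 concave
# (back-loaded); gamma must be nonzero.

#' Uniform accrual pattern
#'
#' @param R recruitment duration (> 0)
#' @return an `accrual_pattern` object
#' @export
accrual_uniform <- function(R) {
  check_pos(R, "R")
  structure(list(kind = "uniform", R = R, gamma = NULL),
            class = "accrual_pattern")
}

#' Truncated-exponential accrual pattern
#'
#' Arrival-time CDF `F(t) = (1 - exp(-gamma t)) / (1 - exp(-gamma R))` on
#' `[0, R]`; convex (fast early recruitment) for `gamma > 0`, concave (slow
#' early recruitment) for `gamma < 0`.
#'
#' @param R recruitment duration (> 0)
#' @param gamma shape parameter, nonzero
#' @return an `accrual_pattern` object
#' @export
accrual_trunc_exp <- function(R, gamma) {
  check_pos(R, "R")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma == 0)
    stop_invalid("`gamma` must be a single nonzero number (use accrual_uniform() for the flat pattern)")
  structure(list(kind = "truncated_exponential", R = R, gamma = gamma),
            class = "accrual_pattern")
}

#' @export
print.accrual_pattern <- function(x, ...) {
  cat(sprintf("Accrual pattern: %s over [0, %g]%s\n", x$kind, x$R,
              if (!is.null(x$gamma)) sprintf(", gamma = %g", x$gamma) else ""))
  invisible(x)
}

#' Accrual cumulative distribution function
#'
#' @param pattern an `accrual_pattern`
#' @param t vector of times
#' @return `P(arrival <= t)` for each element of `t`
#' @export
accrual_cdf <- function(pattern, t) {
  stopifnot(inherits(pattern, "accrual_pattern"))
  tt <- pmin(pmax(t, 0), pattern$R)
  if (pattern$kind == "uniform") return(tt / pattern$R)
  g <- pattern$gamma
  (1 - exp(-g * tt)) / (1 - exp(-g * pattern$R))
}

#' Accrual quantile function
#'
#' Inverse of [accrual_cdf()]; used for inverse-CDF sampling of arrival
#' times. As `gamma -> 0` the truncated-exponential quantile converges to
#' the uniform quantile `u * R`.
#'
#' @param pattern an `accrual_pattern`
#' @param u vector of probabilities in \[0, 1\]
#' @return arrival times in `[0, R]`
#' @export
accrual_quantile <- function(pattern, u) {
  stopifnot(inherits(pattern, "accrual_pattern"))
  if (any(u < 0 | u > 1)) stop_invalid("`u` must lie in [0, 1]")
  if (pattern$kind == "uniform") return(u * pattern$R)
  g <- pattern$gamma
  -log(1 - u * (1 - exp(-g * pattern$R))) / g
}

#' Sample sorted arrival times
#'
#' Draws `n` arrival times over the recruitment window by inverse-CDF
#' transform of uniform variates and returns them sorted (enrollment order).
#'
#' @param n number of prospective patients (>= 1)
#' @param pattern an `accrual_pattern`
#' @return sorted numeric vector of `n` calendar times in `[0, R]`
#' @export
sample_arrival_times <- function(n, pattern) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("`n` must be a positive count")
  sort(accrual_quantile(pattern, stats::runif(n)))
}
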