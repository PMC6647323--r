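# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Patient and event targets are integerized with round-half-up (so
#' 0.5 * 330 = 165 exactly and 82.5 -> 83), not banker's rounding.
#'
#' @param x numeric vector
#' @return numeric vector of integers (as doubles)
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

stop_invalid <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1)))
    stop_invalid(sprintf("`%s` must be a probability in %s, got %s",
                         name, if (open) "(0, 1)" else "[0, 1]",
                         paste(format(x), collapse = ", ")))
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid(sprintf("`%s` must be a single positive number", name))
  invisible(x)
}

# Clip p-values away from 0 and 1 so qnorm() stays finite.
P_CLIP <- 1e-15

clip_p <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    warning("p-value(s) at or beyond [0, 1] clipped to the open interval",
            call. = FALSE)
    p <- pmin(pmax(p, P_CLIP), 1 - P_CLIP)
  }
  p
}

# Independent child seeds for replicate streams, derived once from the
# master seed. Kept strictly below 2^31 (R integers are 32-bit).
child_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n, replace = FALSE)
}
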