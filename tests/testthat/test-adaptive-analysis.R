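# Stage-wise tests, interim decision rule, combination test, Hochberg
# intersection, and closure logic.

test_that("one-sided log-rank matches the hand-computed risk-set table", {
  d <- make_stage_data(c(1, 2, 3, 4), 1,
                       c("control", "control", "experimental", "experimental"))
  p <- one_sided_logrank_p(d)
  expect_equal(attr(p, "z"), 1.697749, tolerance = 1e-4)
  expect_equal(as.numeric(p), 0.0447775, tolerance = 1e-4)
  o <- logrank_oracle(d$time, d$event, d$arm)
  expect_equal(attr(p, "z"), o$z, tolerance = 1e-10)
  expect_equal(as.numeric(p), o$p, tolerance = 1e-10)
})

test_that("log-rank is symmetric under identical arms and arm swap", {
  d <- make_stage_data(rep(c(1, 2, 3), 2), 1,
                       rep(c("control", "experimental"), each = 3))
  expect_equal(as.numeric(one_sided_logrank_p(d)), 0.5)

  set.seed(4)
  d2 <- sim_two_arm_exp(15, 1, 0.5)
  p <- as.numeric(one_sided_logrank_p(d2))
  d2_swapped <- d2
  d2_swapped$arm <- ifelse(d2$arm == "control", "experimental", "control")
  expect_equal(as.numeric(one_sided_logrank_p(d2_swapped)), 1 - p,
               tolerance = 1e-12)
})

test_that("log-rank agrees with the oracle on random censored fixtures", {
  set.seed(11)
  for (i in 1:5) {
    d <- sim_two_arm_exp(12, 1, 0.6)
    d$event[sample.int(24, 5)] <- 0L  # arbitrary censoring
    if (sum(d$event) == 0) next
    p <- one_sided_logrank_p(d)
    o <- logrank_oracle(d$time, d$event, d$arm)
    expect_equal(attr(p, "z"), o$z, tolerance = 1e-8)
  }
})

test_that("log-rank rejects degenerate inputs", {
  expect_error(one_sided_logrank_p(make_stage_data(1:3, 1, rep("control", 3))),
               "each arm")
  expect_error(one_sided_logrank_p(make_stage_data(1:4, 0,
               rep(c("control", "experimental"), 2))), "at least one event")
})

test_that("Cox hazard ratio matches the partial-likelihood grid oracle", {
  d <- make_stage_data(rep(c(1, 2, 3), 2), 1,
                       rep(c("control", "experimental"), each = 3))
  expect_equal(estimate_hazard_ratio(d), 1.0, tolerance = 1e-8)

  set.seed(21)
  checked <- 0
  while (checked < 4) {
    d6 <- sim_two_arm_exp(3, 1, 0.4)
    # a finite partial-likelihood maximum needs event times that are not
    # completely separated between arms
    te <- d6$time[d6$arm == "experimental"]; tc <- d6$time[d6$arm == "control"]
    if (min(te) > max(tc) || min(tc) > max(te)) next
    hr <- estimate_hazard_ratio(d6)
    expect_equal(hr, cox_grid_oracle(d6$time, d6$event, d6$arm),
                 tolerance = 1e-4)
    checked <- checked + 1
  }
})

test_that("Cox estimate is consistent at large n", {
  set.seed(31)
  d <- sim_two_arm_exp(5000, 1, 0.5)
  expect_equal(estimate_hazard_ratio(d), 0.5, tolerance = 0.02)
})

test_that("monotone likelihood returns a capped, flagged estimate", {
  d <- make_stage_data(c(1, 2, 3, 4), c(1, 1, 0, 0),
                       c("control", "control", "experimental", "experimental"))
  expect_warning(hr <- estimate_hazard_ratio(d, cap = 100), "capped")
  expect_equal(hr, 1 / 100)
  d$arm <- rev(d$arm)
  expect_warning(hr2 <- estimate_hazard_ratio(d, cap = 100), "capped")
  expect_equal(hr2, 100)
})

test_that("interim decision rule covers all branches including ties", {
  expect_equal(interim_decision(1.2, 1.1, 1, 1), "futility")
  expect_equal(interim_decision(0.9, 1.3, 1, 1), "continue_O")
  expect_equal(interim_decision(0.9, 0.1, 1, 1), "continue_O")
  expect_equal(interim_decision(1.05, 0.8, 1, 1), "enrich_P")
  # an estimate exactly at its threshold counts as not beneficial
  expect_equal(interim_decision(1.0, 1.0, 1, 1), "futility")
  expect_equal(interim_decision(1.0, 0.9, 1, 1), "enrich_P")
  expect_error(interim_decision(-1, 1), "positive")
})

test_that("combination statistic evaluates the weighted inverse-normal form", {
  w <- combination_weights(135, 135)
  c0 <- combination_statistic(0.5, 0.5, w)
  expect_equal(c0$statistic, 0)
  expect_false(c0$reject)

  c1 <- combination_statistic(0.025, 0.025, w)
  expect_equal(c1$statistic, 2.771808, tolerance = 1e-5)
  expect_true(c1$reject)

  # nearly degenerate stage-2 weight: C collapses to the stage-1 quantile
  expect_equal(combination_statistic(0.01, 0.5, combination_weights(1e6, 1))$statistic,
               qnorm(0.99), tolerance = 1e-3)

  expect_warning(cc <- combination_statistic(0, 0.5, w), "clipped")
  expect_true(is.finite(cc$statistic))
})

test_that("statistic-scale and p-value-scale rejection rules coincide", {
  w <- combination_weights(90, 180)
  set.seed(8)
  p1 <- runif(200); p2 <- runif(200)
  for (i in seq_along(p1)) {
    ct <- combination_statistic(p1[i], p2[i], w, alpha = 0.025)
    expect_identical(ct$reject, ct$p_value < 0.025)
  }
})

test_that("Hochberg intersection p-value matches the printed rule", {
  expect_equal(hochberg_intersection_p(0.01, 0.03), 0.02)
  expect_equal(hochberg_intersection_p(0.5, 0.5), 0.5)
  expect_equal(hochberg_intersection_p(0.04, 0.012), 0.024)
  set.seed(15)
  a <- runif(500); b <- runif(500)
  expect_equal(hochberg_intersection_p(a, b), hochberg_intersection_p(b, a))
  expect_true(all(hochberg_intersection_p(a, b) >= pmin(a, b)))
  expect_true(all(hochberg_intersection_p(a, b) <= 1))
})

test_that("closed testing follows the closure principle on both paths", {
  w <- combination_weights(135, 135)
  none <- closed_testing_decision(0.5, 0.5, 0.5, 0.5, "continue_O", w)
  expect_false(none$rejected_O || none$rejected_P)

  both <- closed_testing_decision(0.005, 0.005, 0.005, 0.005, "continue_O", w)
  expect_true(both$rejected_O && both$rejected_P)
  # equal elementary p-values: intersection p = min(2p, p) = p per stage
  expect_equal(both$tests$intersection$statistic,
               combination_statistic(0.005, 0.005, w)$statistic)

  # closure gate: O combination passes but the intersection fails
  # (per-stage intersection p = min(2 * 0.045, 0.9) = 0.09)
  gate2 <- closed_testing_decision(p1_O = 0.045, p2_O = 0.045,
                                   p1_P = 0.90, p2_P = 0.90,
                                   path = "continue_O", w)
  expect_true(gate2$tests$O$reject)
  expect_false(gate2$tests$intersection$reject)
  expect_false(gate2$rejected_O)

  enr <- closed_testing_decision(p1_O = 0.05, p1_P = 0.004, p2_P = 0.004,
                                 path = "enrich_P", weights = w)
  expect_false(enr$rejected_O)  # O can never be rejected after enrichment
  expect_true(enr$rejected_P)

  fut <- closed_testing_decision(path = "futility", weights = w)
  expect_false(fut$rejected_O || fut$rejected_P)

  expect_error(closed_testing_decision(p1_O = 0.1, path = "continue_O",
                                       weights = w), "required")
})

test_that("rejecting an elementary hypothesis implies the intersection passed", {
  w <- combination_weights(135, 135)
  set.seed(23)
  for (i in 1:200) {
    p <- runif(4, 0.001, 0.999)
    fd <- closed_testing_decision(p[1], p[2], p[3], p[4], "continue_O", w)
    if (fd$rejected_O || fd$rejected_P)
      expect_true(fd$tests$intersection$reject)
  }
})
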