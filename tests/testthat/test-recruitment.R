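# Enrollment-eligibility logic of the recruitment strategies.

# 330 prospective arrivals on a uniform grid over [0, 6]; stage-1 target
# 165 so stage-1 recruitment ends at the 165th arrival.
fixture_stream <- function() make_stream(330, seq(0, 6, length.out = 330), seed = 2)

test_that("futility enrollment counts reproduce the printed extremes", {
  s <- fixture_stream()
  cut <- s$arrival_time[165] + 0.5
  dec <- cut + 0.2

  typ <- apply_strategy(s, strategy_spec("typical", 165), cut, "futility", dec)
  expect_equal(sum(typ$enrolled), 165)
  expect_equal(sum(typ$cohort == "stage1", na.rm = TRUE), 165)

  # with every remaining arrival before the decision time, continued
  # recruitment from P enrolls the stage-1 cohort plus all remaining
  # positives: 165 + 82 = 247
  late_dec <- max(s$arrival_time) + 1
  cp <- apply_strategy(s, strategy_spec("continued_P", 165), cut, "futility",
                       late_dec)
  expect_equal(sum(cp$enrolled), 247)

  co <- apply_strategy(s, strategy_spec("continued_O", 165), cut, "futility",
                       late_dec)
  expect_equal(sum(co$enrolled), 330)
})

test_that("a continue-O decision enrolls the full pool whenever all arrive", {
  s <- fixture_stream()
  cut <- s$arrival_time[165] + 0.5
  dec <- cut + 0.2
  for (nm in c("typical", "continued_O")) {
    log <- apply_strategy(s, strategy_spec(nm, 165), cut, "continue_O", dec)
    expect_equal(sum(log$enrolled), 330)
  }
  # continued_P loses the negatives that arrived while only positives were
  # eligible (skipped patients are not replaced), so the pool is short by
  # exactly the window negatives; with an empty window it refills to 330
  log_p <- apply_strategy(s, strategy_spec("continued_P", 165), cut, "continue_O", dec)
  window_neg <- s$arrival_time > s$arrival_time[165] & s$arrival_time <= dec &
    s$biomarker == "negative"
  expect_equal(sum(log_p$enrolled), 330 - sum(window_neg))
  log_p0 <- apply_strategy(s, strategy_spec("continued_P", 165),
                           s$arrival_time[165], "continue_O", s$arrival_time[165])
  expect_equal(sum(log_p0$enrolled), 330)
})

test_that("strategy ordering holds under futility on random streams", {
  for (seed in 1:6) {
    s <- make_stream(330, sort(runif(330, 0, 6)), seed = seed)
    cut <- s$arrival_time[165] + runif(1, 0, 2)
    dec <- cut + 0.2
    n <- sapply(c("typical", "continued_P", "continued_O"), function(nm)
      sum(apply_strategy(s, strategy_spec(nm, 165), cut, "futility", dec)$enrolled))
    expect_true(n[["typical"]] <= n[["continued_P"]])
    expect_true(n[["continued_P"]] <= n[["continued_O"]])
    # window accounting: continued_P adds exactly the window positives
    window <- s$arrival_time > s$arrival_time[165] & s$arrival_time <= dec
    expect_equal(n[["continued_P"]], 165 + sum(window & s$biomarker == "positive"))
    expect_equal(n[["continued_O"]], 165 + sum(window))
  }
})

test_that("positive enrollment never exceeds the prevalence ceiling", {
  s <- fixture_stream()
  cut <- s$arrival_time[165] + 1
  for (nm in c("typical", "continued_O", "continued_P"))
    for (dec in c("futility", "continue_O", "enrich_P")) {
      log <- apply_strategy(s, strategy_spec(nm, 165), cut, dec, cut + 0.2)
      expect_lte(sum(log$enrolled & log$biomarker == "positive"), 165)
    }
})

test_that("typical recruitment defers arrivals by the halt duration", {
  s <- fixture_stream()
  cut <- s$arrival_time[165] + 1
  dec <- cut + 0.2
  log <- apply_strategy(s, strategy_spec("typical", 165), cut, "continue_O", dec)
  st2 <- log$enrolled & log$cohort == "stage2"
  shift <- dec - s$arrival_time[165]
  expect_equal(log$enrollment_time[st2], s$arrival_time[st2] + shift)
  expect_true(all(log$enrollment_time[st2] > dec))
  # inter-arrival gaps preserved
  expect_equal(diff(log$enrollment_time[st2]), diff(s$arrival_time[st2]))
})

test_that("zero decision period and instantaneous interim align all strategies", {
  s <- fixture_stream()
  cut <- s$arrival_time[165]
  logs <- lapply(c("typical", "continued_O", "continued_P"), function(nm)
    apply_strategy(s, strategy_spec(nm, 165, decision_period = 0), cut,
                   "continue_O", cut))
  expect_equal(logs[[1]]$enrolled, logs[[2]]$enrolled)
  expect_equal(logs[[1]]$enrollment_time, logs[[2]]$enrollment_time)
  expect_equal(logs[[2]]$enrollment_time, logs[[3]]$enrollment_time)
})

test_that("enrichment censoring curtails negatives but keeps observed events", {
  s <- fixture_stream()
  cut <- s$arrival_time[165] + 0.5
  dec <- cut + 0.2
  log <- apply_strategy(s, strategy_spec("typical", 165), cut, "enrich_P", dec)
  cens <- censor_negatives_on_enrichment(log, dec)
  neg1 <- cens$enrolled & cens$biomarker == "negative" & cens$cohort == "stage1"
  expect_equal(sum(neg1), 82)  # the stage-1 negative stratum
  expect_true(all(cens$censoring_time[neg1] == dec))
  expect_true(all(is.infinite(cens$censoring_time[cens$biomarker == "positive"])))

  # an event that happened before the decision is still an event
  sd1 <- stage_data(cens, dec + 5, "O", "stage1")
  early <- cens$enrolled & cens$biomarker == "negative" &
    cens$enrollment_time + cens$latent_event_time <= dec
  expect_gte(sum(early), 1)
  expect_equal(sum(sd1$event[sd1$biomarker == "negative"]), sum(early))

  # contract violation outside the enrichment path
  log_f <- apply_strategy(s, strategy_spec("typical", 165), cut, "futility", dec)
  expect_error(censor_negatives_on_enrichment(log_f, dec), "enrich_P")

  # a log with no negatives is unchanged
  pos_stream <- make_stream(10, 1:10, seed = 3, prevalence = 0.999)
  log_p <- apply_strategy(pos_stream, strategy_spec("typical", 5), 6, "enrich_P", 6.2)
  expect_equal(censor_negatives_on_enrichment(log_p, 6.2)$censoring_time,
               log_p$censoring_time)
})

test_that("anticipated enrollment minima match the closed-form counts", {
  d <- trial_design()
  expect_equal(anticipated_min_enrolled(d, "typical"), 165L)
  expect_equal(anticipated_min_enrolled(d, "continued_P"), 247L)
  expect_equal(anticipated_min_enrolled(d, "continued_O"), 330L)
  expect_equal(expected_positives_non_enriched(d), 165L)
})

test_that("apply_strategy validates its inputs", {
  s <- fixture_stream()
  expect_error(apply_strategy(s[1:100, ], strategy_spec("typical", 165),
                              3, "futility", 3.2), "shorter")
  expect_error(apply_strategy(s, strategy_spec("typical", 165), 3, "futility",
                              2.8), "decision_time")
})
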