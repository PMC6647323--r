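---
title: "Methods: simulating recruitment strategies in adaptive enrichment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating recruitment strategies in adaptive enrichment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichsim)
```

## The design being simulated

`enrichsim` models a randomized, parallel-group, two-arm confirmatory
trial with a time-to-event endpoint in an overall population *O* that
contains a biomarker-positive subgroup *P* (prevalence 50% by default) and
its complement *N*. The trial has two stages. Stage 1 recruits half the
planned total sample size (TSS = 330 by default). When half of the
planned 270 events have accrued in the stage-1 cohort, an interim analysis
estimates Cox hazard ratios for *O* and for *P* and applies a threshold
rule (thresholds `eta_O = eta_P = 1.00`):

* **futility** — both estimates at or above their thresholds: the trial
  stops, nothing is rejected;
* **continue O** — the *O* estimate is below `eta_O` (regardless of *P*):
  stage 2 recruits from all of *O*;
* **enrich P** — otherwise: stage 2 recruits only biomarker-positives, and
  follow-up of every enrolled negative is curtailed at the decision time.

The decision is enacted `decision_period = 0.2` time units after the
interim data cut (the data-lock/review lag). The final analysis is
event-driven: 270 events over all enrolled patients on the continue-O
path, or — once negatives are censored — the prevalence-scaled target of
135 events among enrolled positives on the enrichment path.

Confirmatory testing combines stage-wise one-sided log-rank p-values with
the weighted inverse-normal combination test, rejecting when
$C(p_1,p_2) = w_1\Phi^{-1}(1-p_1) + w_2\Phi^{-1}(1-p_2) > \Phi^{-1}(1-\alpha)$.
The weights $w_k = \sqrt{I_k/\sum_j I_j}$ come from the *planned*
stage-wise event counts (135/135 by default, so $w_1 = w_2 = \sqrt{0.5}$)
and are never re-estimated from observed data — pre-specification is what
makes the combination test valid under adaptation. Multiplicity over
$H_0^O$ and $H_0^P$ is controlled by the closure principle with the
Hochberg intersection p-value
$p^{O,P} = \min[2\min(p^O,p^P), \max(p^O,p^P)]$. On the enrichment path
$H_0^O$ can no longer be rejected; $H_0^P$ requires both
$C(p_1^{O,P}, p_2^P)$ and $C(p_1^P, p_2^P)$ to pass. Stage membership is
by *recruitment* stage: a stage-1 patient whose event occurs during stage
2 still contributes to the stage-1 p-value, which is computed from the
stage-1 cohort's data accumulated through the final data cut. Stage-wise
p-values are clipped to $[10^{-15}, 1-10^{-15}]$ before the normal-quantile
transform.

Some texts state the combination rejection rule on the statistic scale
(as above) and elsewhere as "$C < \alpha$", conflating the statistic with
its p-value transform $1-\Phi(C)$. The two are equivalent;
`combination_statistic()` returns both, and a property test asserts the
equivalence on random inputs.

## Recruitment strategies

All strategies enroll the first `stage1_target` arrivals as the stage-1
cohort; they differ in the *waiting window* between the end of stage-1
recruitment and the enactment of the decision:

* `typical` — accrual freezes: pending arrivals are deferred by the halt
  duration with inter-arrival gaps preserved, then filtered by the
  decision (everyone on continue-O, positives on enrichment, nobody on
  futility).
* `continued_O` — arrivals of any biomarker status enroll throughout the
  window; post-decision arrivals are filtered by the decision.
* `continued_P` — from the end of stage-1 recruitment onward only
  positives enroll; after a continue-O decision recruitment reopens to all
  of *O*.
* `non_enriched` — comparator, described below.

Design choices a reader should know, all genuinely open when the package
was designed:

* **Fixed screening pool, no replacement.** Each replicate draws exactly
  TSS prospective arrivals. Negatives skipped by `continued_P` during the
  window are lost, not replaced, so on the continue-O path that strategy
  can finish below the planned TSS — and can then take *longer* than the
  halted strategy to reach 270 events. This is a real cost of the
  "recruit P while waiting" policy under this pool model, visible in the
  summaries.
* **Window enrollees belong to stage 2.** Their data appear only in the
  stage-2 p-values, preserving independence of the stage-wise p-values
  (stage-1 membership is fixed before any stage-2 data exist).
* **Stage-1 recruitment ends on reaching `stage1_target` enrollees**, not
  at a fixed calendar time.
* **Interim events are counted within the stage-1 cohort**, keeping the
  event trigger aligned with the cohort that generates $p_1$.
* **Interim timing and cohort size scale together.** The stage-1 target is
  `round(interim_fraction * TSS)`: at the default 50% timing this is 165,
  and at a 75% interim a fixed 165-patient cohort could never produce the
  203 triggering events, so tying the two fractions is the only coherent
  generalization for the timing study.
* **Ties at the threshold** (estimate exactly equal to `eta`) count as
  "not beneficial", making the decision rule total.
* **Degenerate estimates.** With all events in one arm the partial
  likelihood is monotone; `estimate_hazard_ratio()` returns a capped value
  (default cap 1e3) with a warning, which lands the decision on the
  appropriate side of the threshold. A stage test that is undefined at the
  final cut (no events, single arm) enters the combination test as a
  neutral p = 0.5 inside the engine; the exported test functions instead
  raise errors.

### The non-enriched comparator

The comparator is a group-sequential design with no recruitment halt: all
arrivals enroll, one interim look at the same interim event count (over
all enrolled patients, no decision lag) stops for futility iff the *O*
hazard-ratio estimate is at or above `eta_O`, and otherwise the final
analysis is a plain one-sided log-rank test of *O* at level alpha — no
combination test, no multiplicity. Its final analysis is at the **fixed
calendar horizon R + F** with administrative censoring, which is what
makes R + F the reference total trial period; an event-driven comparator
would run past R + F whenever the treatment works (fewer events than
planned by the horizon). F therefore plays two roles: the calibration
horizon of the survival model everywhere, and the comparator's follow-up
duration; in the adaptive designs patients are followed until the
event-driven data cuts.

## The synthetic patient streams

Each replicate draws a stream of TSS prospective patients:

* **Arrivals** over `[0, R]`, uniform or truncated-exponential
  (`F(t) = (1-e^{-\gamma t})/(1-e^{-\gamma R})`, `gamma = 2` front-loaded,
  `-2` back-loaded), sampled by inverse-CDF transform.
* **Biomarker status**: deterministic by default — patient *i* is positive
  iff the running quota `round(i * prevalence)` increments — so every
  even-sized prefix carries the prevalence exactly (83 positives among the
  first 165, 82 among the rest). This is what makes the closed-form
  enrollment minima (165, 247, 83) exact rather than distributional; an
  iid Bernoulli mode is available.
* **Allocation**: alternating experimental/control within each biomarker
  stratum (permuted blocks of 2, exact balance); simple randomization
  optional.
* **Event times**: exponential from enrollment, with the control hazard
  calibrated so control survival at F equals 20%
  (`-log(0.2)/F`) and subgroup hazard ratios applied multiplicatively.
  The event-time family is a modeling choice: exponential is the simplest
  distribution consistent with a constant hazard ratio and a single
  calibration anchor.

What the generator does *not* emulate — and hence what passing tests do
not establish about real trials: dropout and loss to follow-up,
non-proportional or time-varying hazards, cure fractions, delayed
biomarker ascertainment, staggered site activation, or misclassified
biomarker status. All durations share one abstract time unit
(interpretable as years).

Seeding: a master seed spawns one child seed per replicate
(`sample.int(2^31 - 2)`); the stream is generated once per replicate and
reused across strategies (common random numbers), so strategy contrasts
are paired and runs are byte-reproducible.

## Numerical choices

* Patient/event targets integerize by round-half-up (`floor(x + 0.5)`).
* Cox fits use Efron tie handling; with continuous simulated times ties
  have probability zero, so the brute-force Breslow grid oracle in the
  tests agrees to 1e-4.
* The one-sided log-rank p-value is `1 - pnorm(Z)` with `Z` oriented so
  positive values favor the experimental arm.
* If the final event target becomes unreachable (possible for
  `continued_P` after a continue-O decision with a depleted pool), the
  final cut falls at the last attainable event with a warning.

## Problem sizes in the test suite

The packaged checks run 1000 replicates for the enrollment-extreme checks
(Scenario 5, (R, F) = (6, 2)), 2000 for the global-null familywise-error
check, 200–300 for directional claims (comparator horizon, interim-timing
trade-off, scenario monotonicity), and 1e4–1e5 draws for distributional
calibration of the generator — sizes chosen so the full suite completes in
a few minutes while keeping Monte-Carlo standard errors well inside the
asserted tolerances (e.g. binomial SE ≈ 0.0035 on the familywise error at
2000 replicates against a slack of 3 SEs).

## Known limitations

* Two stages, one biomarker, one experimental arm; no efficacy stopping at
  the interim (futility only), no alpha-spending boundaries, no
  sample-size re-estimation, no estimation-bias adjustment after
  adaptation.
* The minimum positive-patient count of 83 (the stage-1 positive stratum)
  is attained only by the halted strategy: under this pool model the
  continued strategies always add waiting-window positives before a
  futility stop, so their minima sit higher (~107 at (R, F) = (6, 2) with
  uniform accrual).
* Operating characteristics at 200–2000 replicates carry visible
  Monte-Carlo noise; decision probabilities and extremes stabilize at the
  10^4-replicate scale.
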