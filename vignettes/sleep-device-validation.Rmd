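---
title: "Validating wearable sleep staging against polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable sleep staging against polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A wrist-worn device classifies every 30-second epoch of a night into four
sleep-related stages (wake, light sleep, deep sleep, REM), while laboratory
polysomnography (PSG) — the reference standard — scores the same epochs into
five AASM stages (W, N1, N2, N3, R). Before such a device can be used to
track sleep outside the laboratory, its output must be compared to PSG at
two levels:

1. **epoch by epoch** — does the device label individual epochs correctly?
2. **night by night** — do the overnight summaries derived from its
   hypnogram (total sleep time, wake after sleep onset, sleep efficiency,
   sleep onset latency, number of awakenings, stage durations) agree with
   the PSG-derived summaries?

`sleepval` implements this validation pipeline end to end: hypnogram
containers and epoch CSV I/O, stage-scheme collapsing (N1/N2 → light,
N3 → deep), overnight measure derivation, discrimination and agreement
statistics with participant-level cluster-bootstrap intervals, and
Bland–Altman analysis with assumption-driven limits of agreement. A
Markov-chain simulator generates paired cohorts with known ground truth so
that every stage of the pipeline is testable without access to clinical
data.

## Epoch-level agreement

All epoch analyses are confined to the in-bed window (lights-off to
lights-on), on a 0-based, half-open epoch grid: epoch $i$ covers
$[t_0 + i\,\Delta,\; t_0 + (i+1)\Delta)$ with $\Delta = 30$ s by default.
Epoch length is a parameter rather than a constant so the simulator can
stress-test non-standard grids. Device and reference series are aligned to
the overlap of their windows; epochs missing on either side are masked on
both, and all epoch statistics are pairwise complete (masked epochs are
excluded from confusion tables, with counts reported). The published
protocols we emulate do not describe their missing-epoch convention, so
pairwise-complete deletion is our choice and its footprint is always
visible in the output.

For sleep-vs-wake discrimination, sleep is the positive class:

$$\text{sens} = \frac{TP}{TP+FN},\quad
  \text{spec} = \frac{TN}{TN+FP},\quad
  \text{PPV} = \frac{TP}{TP+FP},\quad
  \text{NPV} = \frac{TN}{TN+FN},$$

computed on epoch counts pooled over participants. Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ is available in two modes: *pooled*
(one kappa on the pooled table) and *average* (kappa per participant, then
the arithmetic mean). The average method excludes participants whose night
is single-class (kappa undefined there); the exclusion count is reported
rather than imputed as zero. Per-stage performance dichotomizes the
4-class data one-vs-rest per stage, reporting average-method kappa and
pooled accuracy, PPV and sensitivity.

### Cluster bootstrap

Epochs within a participant are strongly correlated, so naive binomial
intervals on pooled rates would be far too narrow. Every interval in the
package is therefore a **cluster bootstrap** percentile interval:
participants (not epochs) are resampled with replacement, $n$ per
replicate, the statistic is recomputed, and the 2.5/97.5 percentiles are
taken. We use $B = 1000$ replicates by default and require an explicit
seed; a fixed seed reproduces intervals exactly. Percentile intervals (not
BCa) keep the mechanism transparent; at $n = 41$ clusters they can
undercover mildly, which our own calibration test quantifies (coverage of
an injected pooled sensitivity across 100 simulated cohorts stays above
90%). Mixed-effect regression adjustment of the point estimates is
deliberately not implemented: the bootstrap is the uncertainty mechanism
here, and point estimates are plain pooled rates, which keeps every number
in the report reproducible by hand from the confusion tables.

## Overnight measures

With time in bed $TIB$ = lights-off → lights-on duration:

* sleep onset = first epoch scored as any sleep stage (the common
  device-validation convention; a `first_k_consecutive` rule is available);
* $SOL$ = minutes from lights-off to onset;
* $TST$ = sleep-epoch count × epoch minutes;
* $WASO$ = wake minutes at or after onset (terminal wake before lights-on
  counts, preserving $SOL + TST + WASO = TIB$; excludable by option);
* $SE = 100\,TST/TIB$;
* $NAWK$ = number of maximal contiguous wake runs at or after onset, with
  a configurable minimum run length (default 1 epoch);
* stage durations = per-stage epoch counts × epoch minutes, so
  $TST = \text{light} + \text{deep} + \text{REM}$ holds exactly.

These conventions form a dialect: validation studies rarely publish their
exact onset and awakening rules, so each switch is configurable and the
defaults are the simplest defensible choices. One subtlety found while
testing: relabeling a single wake epoch as sleep always adds one epoch to
TST and never increases WASO, but it can *increase* NAWK by one when it
splits a long awakening in two — the awakening count is not monotone under
single-epoch relabeling.

## Night-level agreement: Bland–Altman with modeled limits

For each continuous measure the per-participant differences
$d_i = \text{device}_i - \text{reference}_i$ are analysed as:

* **mean bias** $\bar d$ (bootstrap CI);
* **proportional bias**: OLS of $d_i$ on the reference value $x_i$;
  declared when the 95% CI of the slope excludes 0. The regressor is the
  reference measurement, not the pair mean, so fitted limits read directly
  as functions of PSG level;
* **normality**: Shapiro–Wilk on the regression residuals at
  $\alpha = 0.05$;
* **heteroscedasticity**: OLS of $|r_i|$ on $x_i$; declared when that
  slope's CI excludes 0.

Limits of agreement then follow a four-case scheme:

| prop. bias | heteroscedastic | 95% limits |
|---|---|---|
| no  | no  | $\bar d \pm 1.96\,SD(d)$ |
| yes | no  | $(b_0 + b_1 x) \pm 1.96\,SD(r)$ |
| no  | yes | $\bar d \pm 2.46\,(c_0 + c_1 x)$ |
| yes | yes | $(b_0 + b_1 x) \pm 2.46\,(c_0 + c_1 x)$ |

where $(c_0, c_1)$ is the absolute-residual regression and
$2.46 = 1.96\sqrt{\pi/2}$ converts a fitted mean absolute deviation into a
95% normal halfwidth. Case selection is driven by the assumption tests but
can be forced through `loa_form`, because published reports mix the forms
in ways that cannot always be reverse-engineered. A fitted halfwidth that
goes negative anywhere on the observed reference range is flagged rather
than clipped. All LOA parameters get bootstrap CIs from jointly resampled
pairs. Degenerate inputs (constant differences, zero-variance reference)
make the affected tests "not applicable" with a recorded reason instead of
a silent 0 or 1.

The awakening count is discrete, so it gets mean and median count
differences plus **linearly weighted kappa** with weights
$w_{ij} = 1 - |i-j|/(K-1)$ over the observed count range; with two
categories this reduces to unweighted kappa, which the tests verify.

## The synthetic cohort

The simulator defines the study conditions for every end-to-end test:

* **reference nights**: first-order Markov chain over W/N1/N2/N3/R,
  starting in W at lights-off, 960 × 30-s epochs (8 h in bed), 41
  participants. The default transition matrix was hand-tuned so cohort
  reference means land near a healthy-adult laboratory night — roughly
  TST 385–390 min, WASO ~65, SOL ~23, SE ~81%, light ~245, deep ~62,
  REM ~80 min;
* **device nights**: each epoch drawn independently from the confusion row
  of the collapsed reference class. The default matrix leaks 0.03 of every
  sleep class to wake (pooled sleep sensitivity 0.97) and keeps 0.70 of
  wake (specificity 0.70), with within-sleep confusions echoing typical
  wearable per-stage sensitivities (light 0.81, deep 0.77, REM 0.84);
* **heterogeneity**: each participant's matrices are redrawn row-wise as
  $\text{Dirichlet}(\phi\, p)$ with concentration $\phi = 400$, which
  reproduces realistic between-participant spread (SD of TST ≈ 60 min)
  while keeping the base matrices as population means;
* **covariates** (age, sex, BMI, skin tone, arm hair density) are drawn
  from simple distributions and exert no effect by default; a
  `subgroup_effect` hook injects performance differences for subgroup
  tests.

Everything is deterministic given the configuration seed; per-participant
streams are derived from it so `simulate_reference`/`simulate_device` are
individually reproducible and compose into `simulate_cohort`.

What the simulator does **not** emulate: temporal clustering of device
errors at stage boundaries (an optional first-order error-persistence
switch exists but defaults to off, so that ground-truth operating
characteristics stay analytic), arousal microstructure, scorer
disagreement, device data dropouts, and any genuine covariate effect on
sleep. Passing tests therefore demonstrate the *statistical machinery* is
correct and calibrated under known truth — not that any particular device
performs well on real patients.

One visible consequence of epoch-independent errors: isolated false-sleep
epochs during the onset period pull the device's sleep-onset latency
toward zero, and isolated false-wake epochs during sleep create many
1-epoch awakenings, so the simulated device's SOL and NAWK are far more
biased than a real device's (whose errors cluster and whose output is
often smoothed). The onset/awakening measures from the simulator exercise
the machinery; they do not imitate a commercial device's post-processing.

## Numerical and design choices

* Undefined ratios (zero denominators) and undefined kappas propagate as
  "undefined with reason"; they are never coerced to 0, and bootstrap
  components that are undefined on the observed data stay undefined while
  a defined statistic failing on most replicates aborts loudly.
* Strict label vocabularies; a user remap table (e.g. `N4 → N3`) handles
  dialects instead of fuzzy matching.
* Subgroup strata below 10 participants are reported as "not evaluated",
  never silently dropped, and no between-group tests are run.
* Problem sizes in the test suite are chosen to keep the full run around a
  minute of default tests plus a few minutes of calibration studies:
  oracle-equivalence fixtures use ≤ 100-epoch nights, the coverage study
  uses 100 default-sized cohorts at $B = 1000$, the bias-recovery study
  200 replicates at $n = 41$, and the false-detection calibration 1000
  replicates.

## Known limitations

* Point estimates are pooled over epochs; no mixed-model marginal
  adjustment is offered.
* Bland–Altman here assumes one night per participant; repeated-nights
  designs need a different (mixed-effects) formulation.
* The percentile bootstrap's mild undercoverage at small cluster counts is
  documented by the calibration test, not corrected (no BCa).
* Sleep-period-time variants of sleep efficiency and multi-bout free-living
  segmentation are out of scope.

## A worked session

```{r example}
library(sleepval)

cfg <- sim_config(seed = 42)              # 41 participants, 8 h in bed
cohort <- simulate_cohort(cfg)
ev <- run_evaluation(cohort, config = list(B = 1000, seed = 42))
ev                                         # printed tables
write_report(ev, "report")                # JSON + CSV mirrors

sg <- subgroup_evaluation(cohort, "sex", config = list(B = 500, seed = 42))
plot(ev$measures$results$tst_min)          # Bland-Altman plot for TST
```
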